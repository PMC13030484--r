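// Seed-and-extend local aligner used for desk-scale chimeric read mapping.
//
// One exported routine aligns a batch of reads against a set of reference
// sequences: exact k-mer seeds on both strands, seeds grouped into chains by
// (reference, diagonal), each chain refined with a banded local alignment
// (match +1, mismatch -2, gap base -3) whose band follows the
// diagonal interpolated between seed anchors.  One maximal-scoring block is
// emitted per chain; read coordinates are reported on the forward-oriented
// read so downstream junction logic is strand-free.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G';
  case 'G': return 'C'; case 'T': return 'A';
  case 'a': return 't'; case 'c': return 'g';
  case 'g': return 'c'; case 't': return 'a';
  default: return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = comp_base(r[i]);
  return r;
}

// log-phase local scoring: random sequence cannot accumulate positive score
static const int MATCH = 1, MISMATCH = -2, GAP = -3;

struct SeedHit { int ref; long pos; };
struct Anchor  { int ref; long diag; int qpos; };

struct Block {
  int read_start, read_end;     // 0-based half-open, strand-oriented for now
  long ref_start, ref_end;      // 0-based half-open
  int matches, score, refidx;
  char strand;
};

// k-mer index over the reference set; k-mers with N are skipped, k-mers seen
// more than max_occ times are dropped (crude repeat masking).
static void build_index(const std::vector<std::string>& refs, int k, int max_occ,
                        std::unordered_map<uint64_t, std::vector<SeedHit> >& idx) {
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  for (size_t r = 0; r < refs.size(); ++r) {
    const std::string& s = refs[r];
    uint64_t km = 0; int valid = 0;
    for (long i = 0; i < (long)s.size(); ++i) {
      int c = base_code(s[i]);
      if (c < 0) { valid = 0; km = 0; continue; }
      km = ((km << 2) | (uint64_t)c) & mask;
      if (++valid >= k) {
        std::vector<SeedHit>& v = idx[km];
        if ((int)v.size() <= max_occ) v.push_back(SeedHit{(int)r, i - k + 1});
      }
    }
  }
  // drop over-represented k-mers entirely
  for (auto it = idx.begin(); it != idx.end(); ) {
    if ((int)it->second.size() > max_occ) it = idx.erase(it);
    else ++it;
  }
}

// Banded local alignment around the chain's interpolated diagonal.
// Returns true and fills blk when a block with positive score is found.
static bool chain_align(const std::string& q, const std::string& ref,
                        std::vector<Anchor>& anchors, int band, Block& blk) {
  const int m = (int)q.size();
  const long Lr = (long)ref.size();
  const int W = 2 * band + 1;

  std::sort(anchors.begin(), anchors.end(),
            [](const Anchor& a, const Anchor& b) { return a.qpos < b.qpos; });

  // drop outlier anchors (chance k-mer repeats) that would bend the band
  // away from the chain's consensus diagonal
  if (anchors.size() > 2) {
    std::vector<long> ds;
    ds.reserve(anchors.size());
    for (const Anchor& a : anchors) ds.push_back(a.diag);
    std::nth_element(ds.begin(), ds.begin() + ds.size() / 2, ds.end());
    long med = ds[ds.size() / 2];
    std::vector<Anchor> kept;
    for (const Anchor& a : anchors) {
      if (a.diag - med <= band && med - a.diag <= band) kept.push_back(a);
    }
    if (!kept.empty()) anchors.swap(kept);
  }

  // piecewise-linear diagonal center per read position
  std::vector<long> center(m);
  {
    size_t a = 0;
    for (int p = 0; p < m; ++p) {
      while (a + 1 < anchors.size() && anchors[a + 1].qpos <= p) ++a;
      long d;
      if (p <= anchors.front().qpos) d = anchors.front().diag;
      else if (p >= anchors.back().qpos || a + 1 >= anchors.size()) d = anchors.back().diag;
      else {
        const Anchor &A = anchors[a], &B = anchors[a + 1];
        d = A.diag + (long)((double)(B.diag - A.diag) *
                            (double)(p - A.qpos) / (double)(B.qpos - A.qpos));
      }
      center[p] = d;
    }
  }

  const int NEG = -1000000000;
  std::vector<int> prev(W, NEG), cur(W, NEG);
  std::vector<long> lo(m, 0);
  std::vector<uint8_t> moves((size_t)m * W, 0);

  int best = 0, best_i = -1; long best_j = -1;

  long prev_lo = 0;
  for (int i = 0; i < m; ++i) {               // DP row i consumes q[i]
    long l = center[i] + i - band;            // ref 0-based window start
    if (l < 0) l = 0;
    long h = center[i] + i + band;            // inclusive
    if (h > Lr - 1) h = Lr - 1;
    lo[i] = l;
    if (l > h) { std::fill(cur.begin(), cur.end(), NEG); std::swap(prev, cur); prev_lo = l; continue; }
    std::fill(cur.begin(), cur.end(), NEG);
    for (long j = l; j <= h; ++j) {
      int off = (int)(j - l);
      // neighbours: out-of-band cells are treated as 0 (a local restart)
      int up = 0, diag = 0, left = 0;
      if (i > 0) {
        long po = j - prev_lo;
        up   = (po >= 0 && po < W && prev[po] != NEG) ? prev[po] : 0;
        long pd = j - 1 - prev_lo;
        diag = (pd >= 0 && pd < W && prev[pd] != NEG) ? prev[pd] : 0;
      }
      if (j > l) left = cur[off - 1]; else left = 0;
      if (left == NEG) left = 0;
      int s = (base_code(q[i]) >= 0 && base_code(q[i]) == base_code(ref[j])) ? MATCH : MISMATCH;
      int vd = diag + s, vu = up + GAP, vl = left + GAP;
      int v = vd; uint8_t mv = 1;
      if (vu > v) { v = vu; mv = 2; }
      if (vl > v) { v = vl; mv = 3; }
      if (v <= 0) { v = 0; mv = 0; }
      cur[off] = v;
      moves[(size_t)i * W + off] = mv;
      if (v > best) { best = v; best_i = i; best_j = j; }
    }
    std::swap(prev, cur);
    prev_lo = l;
  }

  if (best_i < 0) return false;

  // traceback
  int i = best_i; long j = best_j;
  int matches = 0;
  int start_i = i; long start_j = j;
  while (i >= 0 && j >= 0) {
    long off = j - lo[i];
    if (off < 0 || off >= W) break;
    uint8_t mv = moves[(size_t)i * W + off];
    if (mv == 0) { start_i = i + 1; start_j = j + 1; break; }
    if (mv == 1) {
      if (base_code(q[i]) >= 0 && base_code(q[i]) == base_code(ref[j])) ++matches;
      start_i = i; start_j = j;
      --i; --j;
    } else if (mv == 2) { start_i = i; --i; }
    else { start_j = j; --j; }
    if (i < 0 || j < 0) break;
  }

  blk.read_start = start_i;
  blk.read_end   = best_i + 1;
  blk.ref_start  = start_j;
  blk.ref_end    = best_j + 1;
  blk.matches    = matches;
  blk.score      = best;
  return blk.read_end > blk.read_start && blk.ref_end > blk.ref_start && matches > 0;
}

// [[Rcpp::export]]
DataFrame cpp_se_align(CharacterVector read_ids, CharacterVector reads,
                       CharacterVector ref_names, CharacterVector refs,
                       int k, int min_block, int min_score,
                       int band, int diag_gap, int max_chains, int max_occ) {
  std::vector<std::string> R(refs.size());
  for (int i = 0; i < refs.size(); ++i) R[i] = as<std::string>(refs[i]);

  std::unordered_map<uint64_t, std::vector<SeedHit> > idx;
  build_index(R, k, max_occ, idx);
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;

  std::vector<std::string> out_id, out_ref;
  std::vector<int> out_rlen, out_rs, out_re, out_match, out_span, out_score;
  std::vector<double> out_ts, out_te;
  std::vector<std::string> out_strand;

  for (int ri = 0; ri < reads.size(); ++ri) {
    std::string fwd = as<std::string>(reads[ri]);
    std::string id  = as<std::string>(read_ids[ri]);
    int rlen = (int)fwd.size();
    if (rlen < k) continue;

    for (int si = 0; si < 2; ++si) {
      char strand = (si == 0) ? '+' : '-';
      std::string q = (si == 0) ? fwd : revcomp(fwd);

      // collect anchors
      std::vector<Anchor> anchors;
      uint64_t km = 0; int valid = 0;
      for (int p = 0; p < rlen; ++p) {
        int c = base_code(q[p]);
        if (c < 0) { valid = 0; km = 0; continue; }
        km = ((km << 2) | (uint64_t)c) & mask;
        if (++valid >= k) {
          auto it = idx.find(km);
          if (it != idx.end()) {
            int qp = p - k + 1;
            for (const SeedHit& h : it->second)
              anchors.push_back(Anchor{h.ref, h.pos - qp, qp});
          }
        }
      }
      if (anchors.empty()) continue;

      std::sort(anchors.begin(), anchors.end(), [](const Anchor& a, const Anchor& b) {
        if (a.ref != b.ref) return a.ref < b.ref;
        if (a.diag != b.diag) return a.diag < b.diag;
        return a.qpos < b.qpos;
      });

      // split into chains on reference change or diagonal jump
      std::vector<std::pair<size_t, size_t> > chains;   // [begin, end)
      size_t beg = 0;
      for (size_t a = 1; a <= anchors.size(); ++a) {
        if (a == anchors.size() || anchors[a].ref != anchors[beg].ref ||
            anchors[a].diag - anchors[a - 1].diag > diag_gap) {
          chains.push_back(std::make_pair(beg, a));
          beg = a;
        }
      }
      if ((int)chains.size() > max_chains) {
        std::sort(chains.begin(), chains.end(),
                  [](const std::pair<size_t,size_t>& a, const std::pair<size_t,size_t>& b) {
                    return a.second - a.first > b.second - b.first;
                  });
        chains.resize(max_chains);
      }

      for (const auto& ch : chains) {
        std::vector<Anchor> sub(anchors.begin() + ch.first, anchors.begin() + ch.second);
        Block blk;
        if (!chain_align(q, R[sub[0].ref], sub, band, blk)) continue;
        blk.refidx = sub[0].ref;
        blk.strand = strand;
        if (blk.read_end - blk.read_start < min_block) continue;
        if (blk.score < min_score) continue;
        // map to forward-oriented read coordinates
        int rs = blk.read_start, re = blk.read_end;
        if (strand == '-') { rs = rlen - blk.read_end; re = rlen - blk.read_start; }
        // drop exact duplicates (palindromic seeds can reproduce a block)
        bool dup = false;
        for (size_t b = out_id.size(); b-- > 0; ) {
          if (out_id[b] != id) break;
          if (out_rs[b] == rs && out_re[b] == re &&
              out_ref[b] == as<std::string>(ref_names[blk.refidx]) &&
              (long)out_ts[b] == blk.ref_start && (long)out_te[b] == blk.ref_end &&
              out_strand[b][0] == strand) { dup = true; break; }
        }
        if (dup) continue;
        out_id.push_back(id);
        out_rlen.push_back(rlen);
        out_rs.push_back(rs);
        out_re.push_back(re);
        out_strand.push_back(std::string(1, strand));
        out_ref.push_back(as<std::string>(ref_names[blk.refidx]));
        out_ts.push_back((double)blk.ref_start);
        out_te.push_back((double)blk.ref_end);
        out_match.push_back(blk.matches);
        out_span.push_back(re - rs);
        out_score.push_back(blk.score);
      }
    }
  }

  return DataFrame::create(
    _["read_id"] = out_id, _["read_len"] = out_rlen,
    _["read_start"] = out_rs, _["read_end"] = out_re,
    _["strand"] = out_strand, _["ref_name"] = out_ref,
    _["ref_start"] = out_ts, _["ref_end"] = out_te,
    _["matches"] = out_match, _["aligned_span"] = out_span,
    _["score"] = out_score,
    _["stringsAsFactors"] = false);
}
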