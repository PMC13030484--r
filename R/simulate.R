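#' Simulation configuration
#'
#' Bundles the read-simulation parameters that emulate the two library
#' designs: ~10 kb sheared fragments read on a nanopore-like instrument
#' (substitution/insertion/deletion rates approximating modern chemistry),
#' and ~250 bp sonicated fragments read as 150-nt paired ends.  Enrichment is
#' modelled at fragment level: with probability `on_target_fraction` a
#' fragment is drawn from those overlapping the vector cassette, emulating
#' Cas9-guided (long) or hybridization-capture (short) target enrichment.
#'
#' @param seed Integer seed; every generator is reproducible under it.
#' @param long_read List: `mean_len`, `sd_len`, `min_len`, `sub_rate`,
#'   `ins_rate`, `del_rate`.
#' @param short_read List: `fragment_mean`, `fragment_sd`, `read_len`,
#'   `sub_rate`.
#' @param enrichment List: `on_target_fraction` in \[0,1\], optional
#'   `cut_sites` (1-based positions on the vector where Cas9-cut fragment
#'   ends are placed).
#' @return A list of class `aav_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       long_read = list(),
                       short_read = list(),
                       enrichment = list()) {
  cfg <- list(
    seed = as.integer(seed),
    long_read = modifyList(
      list(mean_len = 8000, sd_len = 2000, min_len = 200,
           sub_rate = 0.02, ins_rate = 0.015, del_rate = 0.02),
      long_read),
    short_read = modifyList(
      list(fragment_mean = 250, fragment_sd = 25, read_len = 150,
           sub_rate = 0.001),
      short_read),
    enrichment = modifyList(
      list(on_target_fraction = 0.8, cut_sites = NULL),
      enrichment)
  )
  rates <- c(cfg$long_read$sub_rate, cfg$long_read$ins_rate,
             cfg$long_read$del_rate, cfg$short_read$sub_rate)
  stopifnot(all(rates >= 0), all(rates < 1),
            cfg$enrichment$on_target_fraction >= 0,
            cfg$enrichment$on_target_fraction <= 1,
            cfg$long_read$mean_len > 0, cfg$short_read$fragment_mean > 0)
  structure(cfg, class = "aav_sim_config")
}

#' Simulate a multi-chromosome host genome
#'
#' I.i.d. bases at a requested GC content; a stand-in for a real host
#' assembly at desk scale.
#'
#' @param lengths Integer vector of chromosome lengths.
#' @param gc Target GC fraction.
#' @param seed Integer seed.
#' @param chrom_names Optional names (default chr1, chr2, ...).
#' @return Genome as a named `DNAStringSet`.
#' @export
simulate_host_genome <- function(lengths, gc = 0.41, seed = 1L, chrom_names = NULL) {
  stopifnot(all(lengths > 0), gc >= 0, gc <= 1)
  if (is.null(chrom_names)) chrom_names <- paste0("chr", seq_along(lengths))
  withr::with_seed(seed, {
    seqs <- vapply(lengths, random_dna, character(1), gc = gc)
  })
  as_genome(stats::setNames(seqs, chrom_names), source_label = "simulated host")
}

#' Simulate an ITR-flanked vector
#'
#' Builds a cassette whose terminal segments are GC-rich imperfect
#' palindromes (each ITR's reverse complement matches itself at >= 80%
#' identity, the property that makes real ITRs ambiguous mapping targets)
#' and whose interior is partitioned into promoter/transgene/WPRE-analogue
#' features.  The right ITR is the reverse complement of the left, as in a
#' real ITR-to-ITR cassette.
#'
#' @param length Total cassette length (default 2928, the ITR-to-ITR span of
#'   the emulated vector).
#' @param itr_len ITR length (default 145, the canonical AAV2 value).
#' @param seed Integer seed.
#' @param name Vector sequence name.
#' @return An `aav_vector`.
#' @export
simulate_vector <- function(length = 2928L, itr_len = 145L, seed = 1L, name = "AAV") {
  stopifnot(2 * itr_len < length, itr_len >= 0)
  withr::with_seed(seed, {
    if (itr_len > 0) {
      half <- itr_len %/% 2
      core <- random_dna(half, gc = 0.75)
      mid <- if (itr_len %% 2 == 1) random_dna(1, gc = 0.75) else ""
      left <- paste0(core, mid, revcomp_dna(core))
      # a few point changes keep the palindrome imperfect (>= 80% self-match)
      b <- strsplit(left, "")[[1]]
      nmut <- max(1L, round(0.04 * itr_len))
      at <- sample(itr_len, nmut)
      b[at] <- vapply(b[at], function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
      left <- paste(b, collapse = "")
      right <- revcomp_dna(left)
    } else {
      left <- right <- ""
    }
    interior_len <- length - 2L * itr_len
    interior <- random_dna(interior_len, gc = 0.5)
  })
  p_len <- round(0.25 * interior_len)
  w_len <- round(0.20 * interior_len)
  t_len <- interior_len - p_len - w_len
  f0 <- itr_len
  features <- tibble::tibble(
    label = c("promoter", "transgene", "wpre"),
    start0 = as.integer(c(f0, f0 + p_len, f0 + p_len + t_len)),
    end0 = as.integer(c(f0 + p_len, f0 + p_len + t_len, f0 + interior_len))
  )
  itr <- if (itr_len > 0) {
    tibble::tibble(start0 = as.integer(c(0L, length - itr_len)),
                   end0 = as.integer(c(itr_len, length)))
  } else NULL
  vector_model(name, paste0(left, interior, right), itr = itr, features = features)
}

#' Self reverse-complement identity of each ITR
#'
#' @param vector An `aav_vector`.
#' @return Numeric vector, one identity in \[0,1\] per ITR interval.
#' @export
itr_palindrome_identity <- function(vector) {
  vapply(seq_len(nrow(vector$itr)), function(i) {
    s <- substr(vector$sequence, vector$itr$start0[i] + 1, vector$itr$end0[i])
    a <- strsplit(s, "")[[1]]
    b <- strsplit(revcomp_dna(s), "")[[1]]
    mean(a == b)
  }, numeric(1))
}

#' Describe a planted integration
#'
#' Expresses the integrated structure as an ordered list of oriented vector
#' intervals, so full-length insertions, internal deletions, duplications and
#' head-to-tail concatemers are all representable, together with optional
#' host deletion and junction indels.
#'
#' @param clone_id Clone label.
#' @param chrom Host chromosome.
#' @param pos1 1-based host coordinate; the cassette is inserted immediately
#'   after this base.
#' @param host_deletion Host bases deleted at the junction (>= 0).
#' @param segments Tibble with columns `start0`, `end0`, `orient` ("+"/"-"),
#'   0-based half-open on the vector; default one full-length "+" segment.
#' @param junction_indels Length-2 integer: signed indel at the left and
#'   right junction.  Positive inserts that many random bases; negative trims
#'   that many cassette bases.
#' @param label Free text.
#' @return A list of class `aav_truth`.
#' @export
integration_truth <- function(clone_id, chrom, pos1, host_deletion = 0L,
                              segments = NULL, junction_indels = c(0L, 0L),
                              label = "") {
  stopifnot(length(junction_indels) == 2, host_deletion >= 0)
  if (!is.null(segments)) {
    stopifnot(nrow(segments) >= 1,
              all(c("start0", "end0", "orient") %in% names(segments)),
              all(segments$orient %in% c("+", "-")),
              all(segments$start0 < segments$end0), all(segments$start0 >= 0))
  }
  structure(list(clone_id = clone_id, chrom = chrom, pos1 = as.integer(pos1),
                 host_deletion = as.integer(host_deletion), segments = segments,
                 junction_indels = as.integer(junction_indels), label = label),
            class = "aav_truth")
}

# Extension DP mirroring the aligner's scoring (match +1, mismatch -2, gap
# base -3) and first-maximum tie rule.  a and b are outward-oriented
# continuation strings at a junction; returns the read (i) and reference (j)
# lengths consumed at the maximal-score extension, the score, and the initial
# exact-match run.  This is what converts a planted breakpoint into the
# coordinate an exact-scoring local aligner will report when junction
# microhomology makes the breakpoint ambiguous.
ext_stats <- function(a, b, lim = 60L) {
  av <- strsplit(substr(a, 1, lim), "")[[1]]
  bv <- strsplit(substr(b, 1, lim), "")[[1]]
  la <- length(av); lb <- length(bv)
  run <- 0L
  while (run < min(la, lb) && av[run + 1] == bv[run + 1]) run <- run + 1L
  if (la == 0 || lb == 0) return(list(i = 0L, j = 0L, score = 0L, run = run))
  S <- matrix(0L, la + 1, lb + 1)
  S[, 1] <- -3L * (0:la); S[1, ] <- -3L * (0:lb)
  for (i in seq_len(la)) {
    s <- ifelse(bv == av[i], 1L, -2L)
    for (j in seq_len(lb)) {
      S[i + 1, j + 1] <- max(S[i, j] + s[j], S[i, j + 1] - 3L, S[i + 1, j] - 3L)
    }
  }
  bi <- 0L; bj <- 0L; bs <- 0L
  for (i in 0:la) for (j in 0:lb) {
    if (S[i + 1, j + 1] > bs) { bs <- S[i + 1, j + 1]; bi <- i; bj <- j }
  }
  list(i = bi, j = bj, score = bs, run = run)
}

zero_ext <- list(i = 0L, j = 0L, score = 0L, run = 0L)

rev_chars <- function(x) paste(rev(strsplit(x, "")[[1]]), collapse = "")

#' Plant an integration into a host genome
#'
#' Replaces `host_deletion` bases after `truth$pos1` with the concatenation
#' of the truth's oriented vector segments (junction indels applied) and
#' returns the clone genome together with a junction truth table.  Junction
#' coordinates in the truth table are alignment-resolved: when the cassette
#' end happens to match the adjoining host sequence (incidental junction
#' microhomology), the breakpoint an exact-scoring aligner reports shifts
#' into the homology tract, and the truth table records that coordinate
#' (`pos1`) alongside the raw planted one (`pos1_planted`).
#'
#' @param host Host genome.
#' @param vector An `aav_vector`.
#' @param truth An `aav_truth` from [integration_truth()].
#' @param seed Seed used only when positive junction indels insert random
#'   bases.
#' @return List of class `aav_clone`: `genome` (clone `DNAStringSet`),
#'   `junctions` (tibble, one row per junction side), `cassette` (tibble with
#'   the clone-coordinate cassette interval), `truth`.
#' @export
plant_integration <- function(host, vector, truth, seed = 1L) {
  host <- as_genome(host)
  stopifnot(inherits(vector, "aav_vector"), inherits(truth, "aav_truth"))
  if (!truth$chrom %in% names(host)) stop("chromosome '", truth$chrom, "' not in host", call. = FALSE)
  s <- as.character(host[[truth$chrom]])
  L <- nchar(s)
  vec <- vector$sequence
  Lv <- nchar(vec)
  segs <- truth$segments
  if (is.null(segs)) segs <- tibble::tibble(start0 = 0L, end0 = Lv, orient = "+")
  stopifnot(all(segs$end0 <= Lv))
  pos1 <- truth$pos1; del <- truth$host_deletion
  if (pos1 < 1 || pos1 + del > L - 1) stop("truth out of host bounds", call. = FALSE)

  seg_seq <- vapply(seq_len(nrow(segs)), function(i) {
    x <- substr(vec, segs$start0[i] + 1, segs$end0[i])
    if (segs$orient[i] == "-") revcomp_dna(x) else x
  }, character(1))
  cassette <- paste(seg_seq, collapse = "")

  li <- truth$junction_indels[1]; ri <- truth$junction_indels[2]
  # effective terminal segment intervals after trimming (used for the
  # vector-side breakpoint coordinates)
  first <- as.list(segs[1, ]); last <- as.list(segs[nrow(segs), ])
  if (li < 0) {
    cassette <- substr(cassette, -li + 1, nchar(cassette))
    if (first$orient == "+") first$start0 <- first$start0 - li else first$end0 <- first$end0 + li
  }
  if (ri < 0) {
    cassette <- substr(cassette, 1, nchar(cassette) + ri)
    if (last$orient == "+") last$end0 <- last$end0 + ri else last$start0 <- last$start0 - ri
  }
  ins_l <- ins_r <- ""
  if (li > 0 || ri > 0) {
    withr::with_seed(seed, {
      if (li > 0) ins_l <- random_dna(li)
      if (ri > 0) ins_r <- random_dna(ri)
    })
  }
  cassette <- paste0(ins_l, cassette, ins_r)
  C <- nchar(cassette)
  if (C < 1) stop("junction indels removed the whole cassette", call. = FALSE)

  clone_chrom <- paste0(substr(s, 1, pos1), cassette, substr(s, pos1 + del + 1, L))
  seqs <- as.character(host)
  seqs[truth$chrom] <- clone_chrom
  genome <- as_genome(seqs, source_label = paste0("clone ", truth$clone_id))

  r0 <- pos1 + del + 1                       # first retained host base
  # host-side extensions: cassette continuing vs host reference continuing
  ext_left <- ext_stats(substr(cassette, 1, 60),
                        substr(s, pos1 + 1, min(L, pos1 + 60)))
  ext_right <- ext_stats(rev_chars(substr(cassette, max(1, C - 59), C)),
                         rev_chars(substr(s, max(1, r0 - 60), r0 - 1)))
  # vector-side extensions: host flank continuing vs vector reference beyond
  # the terminal segment boundary (zero when an inserted indel intervenes or
  # the segment reaches the vector end)
  vext_left <- zero_ext
  if (li <= 0) {
    b <- if (first$orient == "+") {
      if (first$start0 > 0) rev_chars(substr(vec, max(1, first$start0 - 59), first$start0)) else ""
    } else {
      if (first$end0 < Lv) comp_dna(substr(vec, first$end0 + 1, min(Lv, first$end0 + 60))) else ""
    }
    if (nzchar(b)) vext_left <- ext_stats(rev_chars(substr(s, max(1, pos1 - 59), pos1)), b)
  }
  vext_right <- zero_ext
  if (ri <= 0) {
    b <- if (last$orient == "+") {
      if (last$end0 < Lv) substr(vec, last$end0 + 1, min(Lv, last$end0 + 60)) else ""
    } else {
      if (last$start0 > 0) rev_chars(comp_dna(substr(vec, max(1, last$start0 - 59), last$start0))) else ""
    }
    if (nzchar(b)) vext_right <- ext_stats(substr(s, r0, min(L, r0 + 59)), b)
  }

  v_left <- if (first$orient == "+") first$start0 + 1 else first$end0
  v_right <- if (last$orient == "+") last$end0 else last$start0 + 1

  pos_eff <- c(pos1 + ext_left$j, r0 - ext_right$j)
  pos_raw <- c(pos1, r0)
  junctions <- tibble::tibble(
    clone_id = truth$clone_id,
    chrom = truth$chrom,
    side = c("left", "right"),
    pos1 = pos_eff,
    pos1_planted = pos_raw,
    vector_pos1 = c(v_left, v_right),
    clone_cass_start1 = pos1 + 1,
    clone_cass_end1 = pos1 + C,
    ext_i = c(ext_left$i, ext_right$i),
    ext_score = c(ext_left$score, ext_right$score),
    ext_run = c(ext_left$run, ext_right$run),
    vext_i = c(vext_left$i, vext_right$i),
    vext_score = c(vext_left$score, vext_right$score),
    vext_run = c(vext_left$run, vext_right$run)
  )
  structure(list(genome = genome, junctions = junctions,
                 cassette = tibble::tibble(chrom = truth$chrom,
                                           start1 = pos1 + 1, end1 = pos1 + C),
                 truth = truth),
            class = "aav_clone")
}

#' @export
print.aav_clone <- function(x, ...) {
  cat("<aav_clone> ", x$truth$clone_id, ": cassette ",
      x$cassette$end1 - x$cassette$start1 + 1, " nt at ",
      x$cassette$chrom, ":", x$truth$pos1, "\n", sep = "")
  invisible(x)
}

other_base <- function(x) {
  vapply(x, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "",
         USE.NAMES = FALSE)
}

mutate_read <- function(x, sub = 0, ins = 0, del = 0) {
  if (sub <= 0 && ins <= 0 && del <= 0) return(x)
  b <- strsplit(x, "")[[1]]
  n <- length(b)
  if (sub > 0) {
    at <- which(runif(n) < sub)
    if (length(at)) b[at] <- other_base(b[at])
  }
  if (del > 0 || ins > 0) {
    keep <- if (del > 0) runif(length(b)) >= del else rep(TRUE, length(b))
    insert <- if (ins > 0) runif(length(b)) < ins else rep(FALSE, length(b))
    pieces <- ifelse(keep, b, "")
    if (any(insert)) {
      pieces[insert] <- paste0(pieces[insert],
                               sample(c("A", "C", "G", "T"), sum(insert), replace = TRUE))
    }
    b <- pieces
  }
  paste(b, collapse = "")
}

# draw one fragment (chrom, start1, end1); on-target fragments are drawn
# uniformly among the starts whose fragment would overlap an enrichment
# region (direct conditional sampling, no rejection loop)
draw_fragment <- function(chrom_names, lens, probs, len, regions, on_target, cut_pos) {
  if (on_target && !is.null(cut_pos)) {
    ri <- 1L
    ci <- match(regions$chrom[ri], chrom_names)
    cl <- lens[ci]
    flen <- min(len, cl)
    cp <- cut_pos[sample.int(length(cut_pos), 1)]
    start <- if (runif(1) < 0.5) cp else cp - flen + 1L
    start <- max(1L, min(start, cl - flen + 1L))
    return(c(ci, start, start + flen - 1L))
  }
  if (on_target && !is.null(regions) && nrow(regions)) {
    ci_all <- match(regions$chrom, chrom_names)
    flen_all <- pmin(len, lens[ci_all])
    lo <- pmax(1L, regions$start1 - flen_all + 1L)
    hi <- pmin(lens[ci_all] - flen_all + 1L, regions$end1)
    w <- pmax(0L, hi - lo + 1L)
    if (sum(w) > 0) {
      ri <- sample.int(nrow(regions), 1, prob = w)
      start <- lo[ri] + sample.int(w[ri], 1) - 1L
      ci <- ci_all[ri]
      return(c(ci, start, start + flen_all[ri] - 1L))
    }
  }
  ci <- sample.int(length(lens), 1, prob = probs)
  cl <- lens[ci]
  flen <- min(len, cl)
  start <- sample.int(cl - flen + 1L, 1)
  c(ci, start, start + flen - 1L)
}

simulate_fragments <- function(genome, n, lengths_fun, config, regions, prefix) {
  chrom_names <- names(genome)
  lens <- Biostrings::width(genome)
  probs <- lens / sum(lens)
  f <- config$enrichment$on_target_fraction
  cut_sites <- config$enrichment$cut_sites
  cut_pos <- NULL
  if (!is.null(cut_sites) && !is.null(regions) && nrow(regions) == 1) {
    cut_pos <- as.integer(regions$start1 - 1L + cut_sites)
  }
  out <- matrix(0L, n, 3)
  want_len <- lengths_fun(n)
  on_target <- if (!is.null(regions)) runif(n) < f else rep(FALSE, n)
  for (i in seq_len(n)) {
    out[i, ] <- draw_fragment(chrom_names, lens, probs, want_len[i],
                              regions, on_target[i], cut_pos)
  }
  tibble::tibble(
    read_id = sprintf("%s_%06d", prefix, seq_len(n)),
    chrom = chrom_names[out[, 1]],
    start1 = out[, 2],
    end1 = out[, 3],
    strand = sample(c("+", "-"), n, replace = TRUE),
    on_target = on_target
  )
}

#' Simulate long reads
#'
#' Samples ~kb-scale fragments (length-weighted across chromosomes, start
#' uniform, optionally enrichment-weighted toward cassette-overlapping
#' fragments), reads each fragment from a random strand, and applies
#' per-base substitution/insertion/deletion errors.
#'
#' @param genome Genome to read from (host or clone).
#' @param n Number of reads.
#' @param config An `aav_sim_config`.
#' @param regions Optional tibble (`chrom`, `start1`, `end1`) of cassette
#'   intervals used for enrichment (e.g. `clone$cassette`).
#' @param junctions Optional junction truth (`clone$junctions`); when given,
#'   a `spans_junction` flag is added to the per-read truth.
#' @param prefix Read-name prefix.
#' @return List with `reads` (named `DNAStringSet`) and `truth` (tibble:
#'   read_id, chrom, start1, end1, strand, on_target\[, spans_junction\]).
#' @export
simulate_long_reads <- function(genome, n, config = sim_config(), regions = NULL,
                                junctions = NULL, prefix = "long") {
  genome <- as_genome(genome)
  stopifnot(n >= 1)
  lr <- config$long_read
  withr::with_seed(config$seed, {
    truth <- simulate_fragments(genome, n, function(m) {
      pmax(lr$min_len, round(rnorm(m, lr$mean_len, lr$sd_len)))
    }, config, regions, prefix)
    ch <- as.character(genome)
    seqs <- substring(ch[truth$chrom], truth$start1, truth$end1)
    rc <- truth$strand == "-"
    seqs[rc] <- revcomp_dna(seqs[rc])
    seqs <- vapply(seqs, mutate_read, character(1),
                   sub = lr$sub_rate, ins = lr$ins_rate, del = lr$del_rate,
                   USE.NAMES = FALSE)
  })
  if (!is.null(junctions)) truth <- annotate_spanning(truth, junctions)
  reads <- Biostrings::DNAStringSet(stats::setNames(seqs, truth$read_id))
  list(reads = reads, truth = truth)
}

#' Simulate short paired-end reads
#'
#' Samples ~250 bp fragments and emits inward-facing R1/R2 mates from
#' opposite fragment ends (reads truncated to the fragment when it is
#' shorter than the read length), with substitution errors only.
#'
#' @inheritParams simulate_long_reads
#' @return List with `r1`, `r2` (named `DNAStringSet`s, names suffixed /1
#'   and /2) and `truth` (fragment-level tibble).
#' @export
simulate_short_pairs <- function(genome, n, config = sim_config(), regions = NULL,
                                 junctions = NULL, prefix = "frag") {
  genome <- as_genome(genome)
  stopifnot(n >= 1)
  sr <- config$short_read
  withr::with_seed(config$seed, {
    truth <- simulate_fragments(genome, n, function(m) {
      pmax(50, round(rnorm(m, sr$fragment_mean, sr$fragment_sd)))
    }, config, regions, prefix)
    ch <- as.character(genome)
    frag <- substring(ch[truth$chrom], truth$start1, truth$end1)
    rc <- truth$strand == "-"
    frag[rc] <- revcomp_dna(frag[rc])
    flen <- nchar(frag)
    rl <- pmin(sr$read_len, flen)
    r1 <- substring(frag, 1, rl)
    r2 <- revcomp_dna(substring(frag, flen - rl + 1, flen))
    if (sr$sub_rate > 0) {
      r1 <- vapply(r1, mutate_read, character(1), sub = sr$sub_rate, USE.NAMES = FALSE)
      r2 <- vapply(r2, mutate_read, character(1), sub = sr$sub_rate, USE.NAMES = FALSE)
    }
  })
  if (!is.null(junctions)) truth <- annotate_spanning(truth, junctions)
  list(
    r1 = Biostrings::DNAStringSet(stats::setNames(r1, paste0(truth$read_id, "/1"))),
    r2 = Biostrings::DNAStringSet(stats::setNames(r2, paste0(truth$read_id, "/2"))),
    truth = truth
  )
}

# per-(read, junction) spanning table; a fragment spans a junction when both
# flanks clear the aligner's minimum block span/score and contain a seed
spanning_table <- function(truth, junctions, min_block = 30, min_score = 30, k = 15) {
  purrr::map_dfr(seq_len(nrow(junctions)), function(i) {
    J <- junctions[i, ]
    need_host <- max(min_block - J$ext_i, min_score - J$ext_score, k - J$ext_run, 1)
    need_vec <- max(min_block - J$vext_i, min_score - J$vext_score, k - J$vext_run, 1)
    cs <- J$clone_cass_start1; ce <- J$clone_cass_end1
    on_chrom <- truth$chrom == J$chrom
    if (J$side == "left") {
      host_nt <- ifelse(on_chrom & truth$start1 <= cs - 1 & truth$end1 >= cs,
                        cs - truth$start1, 0)
      cass_nt <- pmax(0, pmin(truth$end1, ce) - cs + 1)
    } else {
      host_nt <- ifelse(on_chrom & truth$end1 >= ce + 1 & truth$start1 <= ce,
                        truth$end1 - ce, 0)
      cass_nt <- pmax(0, ce - pmax(truth$start1, cs) + 1)
    }
    tibble::tibble(read_id = truth$read_id, chrom = J$chrom, side = J$side,
                   pos1 = J$pos1,
                   spans = host_nt >= need_host & cass_nt >= need_vec)
  })
}

annotate_spanning <- function(truth, junctions, ...) {
  st <- spanning_table(truth, junctions, ...)
  any_span <- st %>%
    dplyr::group_by(.data$read_id) %>%
    dplyr::summarise(spans_junction = any(.data$spans), .groups = "drop")
  dplyr::left_join(truth, any_span, by = "read_id")
}

#' Junction-spanning read counts from simulation truth
#'
#' Counts, per planted junction side, the reads whose fragment geometry makes
#' the junction detectable: both flanks reach the aligner's minimum block
#' span and score (microhomology extensions included) and contain an exact
#' seed k-mer.
#'
#' @param truth Per-read truth tibble from a simulator.
#' @param junctions Junction truth tibble from [plant_integration()].
#' @param min_block,min_score,k Detectability thresholds; defaults match the
#'   internal aligner's defaults.
#' @return `junctions` with `n_spanning` and `spanning_reads` (list) columns.
#' @export
junction_support_truth <- function(truth, junctions, min_block = 30,
                                   min_score = 30, k = 15) {
  st <- spanning_table(truth, junctions, min_block, min_score, k)
  agg <- st %>%
    dplyr::filter(.data$spans) %>%
    dplyr::group_by(.data$chrom, .data$side, .data$pos1) %>%
    dplyr::summarise(n_spanning = dplyr::n_distinct(.data$read_id),
                     spanning_reads = list(unique(.data$read_id)), .groups = "drop")
  out <- dplyr::left_join(junctions, agg, by = c("chrom", "side", "pos1"))
  out$n_spanning[is.na(out$n_spanning)] <- 0L
  out
}

#' Write a junction truth table as TSV / BED
#'
#' @param junctions Junction tibble from [plant_integration()].
#' @param path Output path.
#' @export
write_truth_tsv <- function(junctions, path) {
  readr::write_tsv(junctions, path)
  invisible(path)
}

#' @rdname write_truth_tsv
#' @export
write_truth_bed <- function(junctions, path) {
  bed <- tibble::tibble(chrom = junctions$chrom,
                        start0 = junctions$pos1 - 1L,
                        end0 = junctions$pos1,
                        name = paste(junctions$clone_id, junctions$side, sep = ":"),
                        score = 0L,
                        strand = ifelse(junctions$side == "left", "+", "-"))
  write_bed(bed, path)
}
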