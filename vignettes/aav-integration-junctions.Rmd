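---
title: "Detecting AAV integration junctions from chimeric reads"
author: "aavjunct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting AAV integration junctions from chimeric reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aavjunct)
```

## The problem

Recombinant adeno-associated virus (AAV) vectors mostly persist as episomes,
but a fraction of vector genomes integrates into host chromosomes. Locating
those integration sites matters for gene-therapy safety assessment and for
characterising engineered single-cell clones. The observable signal is the
**vector–host junction**: a sequencing read that carries vector sequence on
one side and host chromosomal sequence on the other. `aavjunct` implements
two complementary junction-calling workflows over a shared alignment-block
representation:

* a **long-read** workflow (Cas9-enrichment/nanopore-style libraries, ~kb
  fragments): split alignments of one molecule become breakend adjacencies;
  vector–host adjacencies are clustered into integration events with
  supporting-read lists, and the best-supported event is designated the
  clone's *baseline* integration site;
* a **short-read** workflow (hybridization-capture/paired-end-style
  libraries, ~250 bp fragments): candidate reads aligning to both
  references are filtered on matched bases and match score, checked for
  proximity and collinearity along the read, and converted into
  orientation-dependent junction coordinates that are aggregated per site.

Both workflows align against a **hybrid reference** — the host assembly
concatenated with the complete vector sequence — so one aligner pass exposes
chimeras, and both are exercised end to end on synthetic data with planted
integrations generated by the package itself.

## Alignment blocks and the match score

All callers consume one tabular type: the *alignment block*, a local
alignment of part of a read to one reference sequence, with read coordinates
always stored on the forward-oriented read so junction adjacency logic is
strand-free. Blocks come from three interchangeable sources: the internal
seed-and-extend aligner, SAM/BAM records (`parse_sam_blocks()`), and BLAT
PSL files (`parse_psl_blocks()`).

Each block carries its matched-base count and aligned span; the **match
score** is their ratio. The short-read filter requires strictly more than
35 matched nucleotides on *both* the host and the vector block (a boundary
the test suite pins down exactly: 35 is rejected, 36 accepted) and a match
score of at least 0.9 on both.

## The internal aligner and its numerical choices

The internal aligner exists so the whole pipeline is testable at desk scale
without external aligner binaries; it is not a performance replacement for a
production long-read aligner. It works in three steps: exact k-mer seeds on
both strands (k = 15 for long reads, 11 for short), grouping of seeds into
chains by reference and diagonal (diagonal jumps above 50 nt start a new
chain, so a 1.3 kb internal deletion or a concatemer junction always
separates chains), and a banded local alignment around the chain's
interpolated diagonal, one maximal-scoring block per chain.

Numerical choices that matter:

* **Scoring is match +1, mismatch −2, gap base −3.** A milder unit-cost
  scheme (+1/−1/−1) sits in the *linear* phase of local alignment for
  4-letter sequences: optimal local scores between unrelated random
  sequences grow linearly (~0.3 per base), so multi-kilobase random regions
  would outscore any threshold and every read would "align" everywhere. The
  chosen scores are in the log phase, where a random extension cannot
  accumulate score, which is also what keeps the untransduced negative
  control clean.
* **Minimum block span 30 nt and minimum local score 30** (a BLAT-style
  minimum output score). Both sit below the callers' own >35 nt filter, so
  filtering remains the caller's decision, while spurious seed extensions —
  which would need +15 of net score from random sequence — are suppressed.
* **Band half-width 100 (long) / 20 (short)** around the chain diagonal,
  covering nanopore-scale indel drift; anchors more than a band-width from
  the chain's median diagonal are discarded before the band is laid out,
  because a chance repeated k-mer can otherwise bend the band away from the
  true diagonal mid-read.
* **Overlap reduction**: the two ITRs of a real vector are near-identical
  (the right ITR is the reverse complement of the left), so one read segment
  routinely gets two vector alignments. Within a read, blocks overlapping a
  better block by more than half the shorter span are dropped; "better" is
  more matches, then longer reference span, then lexicographic order —
  making the reduction deterministic.

The aligner is validated property-style against an exhaustive
Smith–Waterman oracle (`Biostrings::pairwiseAlignment` with the identical
scoring scheme) on hundreds of randomized planted-locus instances, with the
planted mutations kept a few bases away from the segment ends so the optimum
is unique and the comparison is exact.

## Junction coordinates and their conventions

Internally all coordinates are 0-based half-open; everything user-facing is
1-based. The junction coordinate of a call is taken from the host block and
depends on the orientation of the vector segment on the read: if the vector
segment precedes the host block on the forward-oriented read, the junction
is the host block's read-upstream reference boundary, otherwise its
read-downstream boundary, converted through the host strand. `side` records
whether the retained host flank lies left or right of the coordinate. These
conventions are validated against planted simulation truth rather than
against any published convention, because published reports rarely state
whether "the" coordinate is the last host base or the first vector-adjacent
base.

The long-read caller derives one breakend adjacency per consecutive block
pair of a read, keeps those joining one vector and one host breakend within
a 50 nt read gap, and clusters host positions by single linkage at 25 nt
within each (chromosome, side). The representative position is the member
median, taking the lower middle for even counts — the median is robust to
nanopore end jitter, and the deterministic tie rule keeps outputs
byte-reproducible. Exactly one event per clone is flagged as baseline:
maximal support, ties broken toward the tighter cluster, then coordinates.
Entry and exit junctions of one insertion are deliberately reported as two
events (left- and right-side), matching breakpoint-level reporting.

## What the simulator emulates — and what it does not

The synthetic-data module generates every input the pipelines need:

* **Host genomes** with i.i.d. bases at a requested GC content (default
  0.41, a human-like value).
* **Vectors** of configurable length (default 2928 nt, ITR to ITR) whose
  terminal 145 nt are GC-rich imperfect palindromes — each ITR's reverse
  complement matches itself at ≥ 80% identity, and the right ITR is the
  reverse complement of the left, reproducing the mapping ambiguity real
  ITRs cause. The interior is partitioned into promoter/transgene/WPRE
  analogue features.
* **Clone genomes** via `plant_integration()`: an ordered list of oriented
  vector segments (full-length cassettes, internal deletions, duplications,
  head-to-tail concatemers, inversions) replaces `host_deletion` bases at
  the insertion point, with optional junction indels.
* **Reads**: long reads with ~8 kb mean fragments and per-base
  substitution/insertion/deletion errors (defaults 0.02/0.015/0.02,
  approximating modern nanopore chemistry; the source workflows publish no
  read-level error figures, so these are the package's choice and fully
  configurable), and ~250 bp fragments read as 150 nt inward pairs with
  substitution errors only. Quality strings are constant Q20 because no
  downstream step is quality-aware.
* **Enrichment** at fragment level: with probability `on_target_fraction`
  (default 0.8) a fragment is drawn uniformly among the starts overlapping
  the cassette, emulating both Cas9-guided and hybridization-capture
  enrichment; optional cut positions pin fragment ends, emulating Cas9
  cleavage sites.

Two design points deserve emphasis:

**Junction truth is alignment-resolved.** When the cassette end happens to
match the adjoining host sequence (incidental microhomology), the physical
breakpoint is ambiguous within the homology tract, and any exact-scoring
aligner will place the block boundary at the end of the maximal-scoring
extension. `plant_integration()` therefore runs a small extension DP with
the aligner's own scoring and first-maximum tie rule at each junction and
records the resolved coordinate (keeping the raw planted one as
`pos1_planted`). This makes "error-free recovery is exact" a deterministic,
seed-independent property instead of one that fails whenever the first
cassette base happens to equal the first displaced host base (probability
~1/4 per junction).

**"Junction-spanning" is defined by detectability.** A read is flagged as
spanning a junction when both flanks clear the aligner's minimum block span
and score (homology extensions included) and contain an exact seed k-mer.
This is the only definition under which "baseline support equals the number
of junction-spanning reads" is a well-posed equality; a flank of, say, 12 nt
physically spans the junction but cannot be aligned by any k-mer-seeded
method.

What the simulator does **not** model, and what passing tests therefore do
not demonstrate about real data: repeat and segmental-duplication structure
of real genomes (i.i.d. bases make off-target chimeras vastly rarer than in
GRCh38), PCR duplicates and chimera artifacts of library preparation,
coverage bias of capture probes, basecaller-specific error patterns, and
junction microhomology as a biological preference (it arises only
incidentally). Results on real libraries will show lower precision than the
clean simulations here.

## Probe tilings and the validation reference

`design_capture_probes()` tiles fixed-length probes at a fixed step across a
target interval; with 120 nt probes at a 40 nt step, a full-length 2928 bp
cassette yields 71 probes — the worked example pinned in the tests. The
vendor overlap of the emulated design is not published; 40 nt is the step
that reproduces the printed probe count and is configurable.
`build_validation_reference()` assembles host flank + cassette + host flank
(default ±5 kb, clipped at chromosome ends) for inspecting called junctions
against supporting reads in a genome browser; insertion is modelled without
host loss by default, with a `host_deletion` parameter covering the
alternative.

## Evaluation, concordance and problem sizes

`evaluate_against_truth()` matches calls greedily (nearest first, one call
per truth site) within a tolerance and reports precision, recall and
per-site coordinate error; `compare_callsets()` applies the same greedy
matching between the two workflows' callsets and labels sites `both`,
`long_only` or `short_only`. Both are deliberately simple, symmetric
procedures whose properties (symmetry up to labels, monotonicity) are unit
tested.

The test suite and the acceptance script run at desk scale: a 2 × 100 kb
host, one planted single-copy integration, 200 long reads (~8 kb) and 5,000
short fragment pairs, with 200 randomized oracle instances for the aligner.
These sizes were chosen so the whole battery completes in a few minutes on a
single core while every stage still sees tens to hundreds of supporting
reads per junction.

## Known limitations

* The internal aligner emits one block per chain and does not perform
  spliced or multi-part chaining within a chain; highly fragmented reads
  (many error clusters) may lose short middle segments.
* Single-linkage clustering with a 25 nt tolerance can merge two genuine
  integration sites closer than the tolerance; such near-collisions are not
  biologically expected in single-copy clones but can occur in mixed
  populations.
* A read spanning both junctions of one insertion contributes support to
  both the left and right event; the two events are not automatically
  paired (a convenience for doing so exists in `compare_callsets()`-style
  post-processing, not in the caller itself).
* The PSL path trusts BLAT's own match accounting; repMatches are counted
  as matches.
* Vector-side breakpoint coordinates inside ITRs are inherently ambiguous
  because the two ITRs are reverse-complement copies; host-side coordinates
  are unaffected.

## A minimal session

```{r example, eval = FALSE}
host <- simulate_host_genome(c(100000, 100000), gc = 0.41, seed = 1)
vec <- simulate_vector(2928, 145, seed = 1)
clone <- plant_integration(host, vec, integration_truth("clone1", "chr1", 50000))
href <- build_hybrid_reference(host, vec)

sim <- simulate_long_reads(clone$genome, 200,
                           sim_config(seed = 2), regions = clone$cassette,
                           junctions = clone$junctions)
res <- run_long_pipeline(sim$reads, href)
res$events[res$events$is_baseline, ]
autoplot(res$events)

glance(evaluate_against_truth(res$events, clone$junctions))
```
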