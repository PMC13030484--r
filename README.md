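# aavjunct

Detection of adeno-associated virus (AAV) vector integration junctions in a
host genome from chimeric sequencing reads.

AAV vectors persist mostly episomally but occasionally integrate into host
chromosomes. The observable evidence of an integration is the chimeric
read: part vector, part host. `aavjunct` aligns reads against a *hybrid
reference* (host assembly + vector sequence concatenated) and calls
junctions with two complementary workflows:

* **Long reads** (Cas9-enrichment / nanopore-style, ~kb fragments): split
  alignments of one molecule are turned into breakend adjacencies
  `(ref_A, pos_A, side_A) — (ref_B, pos_B, side_B)`; adjacencies joining one
  vector and one host breakend are clustered by single linkage (25 nt) into
  integration events with supporting-read lists, and the event with the
  highest support is flagged the clone's **baseline integration site**.
  Per-read vector structure (internal deletions, duplications, head-to-tail
  concatemers, inversions) is reconstructed from the ordered vector blocks.
* **Short reads** (hybridization-capture / paired-end-style, ~250 bp
  fragments): reads aligning to both references are filtered on matched
  bases (strictly > 35 nt on *both* the host and vector block) and match
  score (matches / aligned span ≥ 0.9), checked for proximity and
  collinearity along the read, and converted into orientation-dependent
  1-based junction coordinates aggregated per `(chrom, pos, side)` with
  supporting-read counts.

The package also contains everything needed to test these callers at desk
scale: a hybrid/validation-reference builder, a capture-probe tiling
utility (120-nt probes at a 40-nt step tile a 2928 bp ITR-to-ITR cassette
into exactly 71 probes), SAM/BAM and BLAT-PSL block importers, and a
synthetic-data module that plants integrations with known truth and
simulates both library designs. All tabular results are tibbles; results
have `autoplot()`, `tidy()` and `glance()` methods.

## Worked example

Simulate a HeLa-like clone carrying one single-copy cassette, sequence it
with long reads, and call the integration site:

```r
library(aavjunct)

host  <- simulate_host_genome(c(100000, 100000), gc = 0.41, seed = 1)
vec   <- simulate_vector(2928, 145, seed = 1)          # ITR-to-ITR cassette
clone <- plant_integration(host, vec, integration_truth("clone1", "chr1", 50000))
href  <- build_hybrid_reference(host, vec)

sim <- simulate_long_reads(clone$genome, 120, sim_config(seed = 2),
                           regions = clone$cassette, junctions = clone$junctions)
res <- run_long_pipeline(sim$reads, href)
tidy(res)[, c("chrom", "pos1", "side", "support", "is_baseline")]
#> # A tibble: 2 × 5
#>   chrom  pos1 side  support is_baseline
#>   <chr> <dbl> <chr>   <int> <lgl>
#> 1 chr1  50000 left       75 TRUE
#> 2 chr1  50000 right      59 FALSE

glance(evaluate_against_truth(res$events, clone$junctions))
#> # A tibble: 1 × 6
#>   n_calls n_matched n_truth precision recall mean_coord_error
#>     <int>     <int>   <int>     <dbl>  <dbl>            <dbl>
#> 1       2         2       2         1      1                0
```

Both junction-side events sit at the planted coordinate (`chr1:50000`,
entry and exit junctions are reported separately); 75 of the 120 reads
span the left junction and support the baseline event; precision and
recall against the planted truth are 1 with zero coordinate error.
`autoplot(res$events)` draws the support plot.

The short-read workflow is symmetric
(`run_short_pipeline(r1, r2, href)`), and externally produced alignments
enter through `parse_sam_blocks()` / `parse_psl_blocks()`.

A thin command-line interface wraps the same functions
(`exec/aavjunct`, installed with the package):

```sh
aavjunct simulate --mode long --out-prefix sim --seed 1
aavjunct call-long --reads sim_long.fastq --host sim_host.fa \
    --vector sim_vector.fa --out-prefix calls
aavjunct compare --long calls_events.tsv --short summary.tsv --out conc.tsv
```

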