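Package: aavjunct
Title: Detection of AAV Vector Integration Junctions from Long- and Short-Read Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects adeno-associated virus (AAV) vector integration sites in a
    host genome from chimeric sequencing reads. Builds hybrid host+vector and
    junction-validation references and capture-probe tilings; simulates clone
    genomes with planted integrations (including concatemers and rearranged
    cassettes) together with long reads and short paired-end reads carrying a
    known truth set; produces alignment blocks from an internal seed-and-extend
    aligner or from SAM/BAM and BLAT PSL files; and calls read-level
    vector-host junctions with two complementary workflows: a long-read
    breakend-pairing and clustering caller with supporting-read ranking, and a
    short-read chimeric-block caller with match-score filtering and
    orientation-dependent junction coordinates. Includes cross-method
    concordance and truth-based evaluation utilities and a command-line
    entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    S4Vectors,
    methods,
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    jsonlite,
    withr,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
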