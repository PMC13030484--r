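#' Reverse complement of DNA strings
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()].
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp_dna("ACGTN")
revcomp_dna <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

comp_dna <- function(x) {
  as.character(Biostrings::complement(Biostrings::DNAStringSet(x)))
}

random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p), collapse = "")
}

#' @keywords internal
aj_log <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message("[aavjunct] ", ...)
}

# stage-count bookkeeping attached to pipeline results
stage_counts <- function(...) {
  x <- c(...)
  tibble::tibble(stage = names(x), n = unname(x))
}
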