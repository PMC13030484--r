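#' Coerce to a genome
#'
#' A genome is represented as a named [Biostrings::DNAStringSet]: an ordered
#' set of uniquely named chromosome/contig sequences over the A,C,G,T,N
#' alphabet.  Both named character vectors and `DNAStringSet` objects are
#' accepted wherever a genome is expected.
#'
#' @param x Named character vector of DNA sequences, or a `DNAStringSet`.
#' @param source_label Free-text provenance label stored in the metadata.
#' @return A validated `DNAStringSet`.
#' @export
as_genome <- function(x, source_label = NULL) {
  g <- if (methods::is(x, "DNAStringSet")) x else Biostrings::DNAStringSet(toupper(unlist(x)))
  validate_genome(g)
  if (!is.null(source_label)) S4Vectors::metadata(g)$source_label <- source_label
  g
}

validate_genome <- function(g) {
  nm <- names(g)
  if (length(g) == 0) stop("genome contains no sequences", call. = FALSE)
  if (is.null(nm) || any(!nzchar(nm))) stop("all genome sequences must be named", call. = FALSE)
  if (anyDuplicated(nm)) {
    stop("duplicate sequence names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  if (any(Biostrings::width(g) < 1)) stop("zero-length sequence in genome", call. = FALSE)
  bad <- setdiff(Biostrings::uniqueLetters(g), c("A", "C", "G", "T", "N"))
  if (length(bad)) stop("genome contains non-ACGTN letters: ", paste(bad, collapse = ","),
                        call. = FALSE)
  invisible(g)
}

#' Read/write genomes as FASTA
#'
#' @param path FASTA file path.
#' @return `read_genome()` returns a `DNAStringSet`; `write_genome()` returns
#'   `path` invisibly.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  as_genome(g)
}

#' @rdname read_genome
#' @param genome Genome to write.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(as_genome(genome), path)
  invisible(path)
}

#' Read/write FASTQ reads
#'
#' Reads are returned as a named `DNAStringSet`; qualities are not retained
#' (no downstream step is quality-aware).
#'
#' @param path FASTQ file path (optionally gzipped).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' @rdname read_fastq
#' @param reads Named `DNAStringSet` (or named character vector) of reads.
#' @param quality Single quality character applied to every base (default
#'   "5", i.e. Q20).
#' @export
write_fastq <- function(reads, path, quality = "5") {
  reads <- if (methods::is(reads, "DNAStringSet")) reads else Biostrings::DNAStringSet(reads)
  q <- Biostrings::BStringSet(strrep(quality, Biostrings::width(reads)))
  Biostrings::writeXStringSet(reads, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Write intervals as BED
#'
#' Writes a (chrom, start0, end0, name, ...) tibble as browser-ready BED text.
#'
#' @param df Tibble with at least `chrom`, `start0`, `end0` columns.
#' @param path Output path.
#' @export
write_bed <- function(df, path) {
  stopifnot(all(c("chrom", "start0", "end0") %in% names(df)))
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}
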