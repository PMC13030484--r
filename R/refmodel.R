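#' Construct a vector model
#'
#' A vector model bundles the vector (cassette) sequence with its inverted
#' terminal repeat (ITR) intervals and interior feature annotations
#' (promoter/transgene/WPRE analogues).  All intervals are 0-based half-open.
#'
#' @param name Sequence name used in hybrid references.
#' @param sequence DNA string of the full ITR-to-ITR cassette.
#' @param itr Tibble with columns `start0`, `end0` holding zero or two ITR
#'   intervals (one at each end, non-overlapping).
#' @param features Tibble with columns `label`, `start0`, `end0`.
#' @return An object of class `aav_vector`.
#' @export
vector_model <- function(name, sequence, itr = NULL, features = NULL) {
  sequence <- toupper(as.character(sequence))
  L <- nchar(sequence)
  if (is.null(itr)) itr <- tibble::tibble(start0 = integer(), end0 = integer())
  if (is.null(features)) features <- tibble::tibble(label = character(),
                                                    start0 = integer(), end0 = integer())
  if (nrow(itr) > 0) {
    stopifnot(nrow(itr) == 2, all(itr$start0 >= 0), all(itr$end0 <= L),
              all(itr$start0 < itr$end0))
    itr <- dplyr::arrange(itr, .data$start0)
    if (itr$end0[1] > itr$start0[2]) stop("ITR intervals overlap", call. = FALSE)
    if (itr$start0[1] != 0 || itr$end0[2] != L)
      stop("ITR intervals must sit at the vector ends", call. = FALSE)
  }
  if (nrow(features) > 0) {
    stopifnot(all(features$start0 >= 0), all(features$end0 <= L))
  }
  structure(list(name = name, sequence = sequence, itr = itr, features = features),
            class = "aav_vector")
}

#' @export
print.aav_vector <- function(x, ...) {
  cat("<aav_vector> ", x$name, ": ", nchar(x$sequence), " nt, ",
      nrow(x$itr), " ITRs, ", nrow(x$features), " features\n", sep = "")
  invisible(x)
}

#' Build a hybrid host+vector reference
#'
#' Concatenates the host assembly and the vector sequence into one alignment
#' target so a single aligner pass exposes chimeric vector-host reads.  Host
#' sequences come first, then the vector; the vector name is recorded so
#' alignment blocks can be classed as vector- or host-derived.
#'
#' @param host Host genome (named `DNAStringSet` or named character vector).
#' @param vector An `aav_vector` (or a single named character sequence).
#' @return An object of class `aav_hybrid_ref` with elements `genome`
#'   (`DNAStringSet`) and `vector_names` (character).
#' @export
#' @examples
#' host <- as_genome(c(chr1 = "ACGTACGTACGT"))
#' vec <- vector_model("AAV", "GGGCCCGGGCCC")
#' href <- build_hybrid_reference(host, vec)
#' names(href$genome)
build_hybrid_reference <- function(host, vector) {
  host <- as_genome(host)
  if (!inherits(vector, "aav_vector")) {
    stopifnot(length(vector) == 1, !is.null(names(vector)))
    vector <- vector_model(names(vector), vector[[1]])
  }
  if (vector$name %in% names(host)) {
    stop("vector name '", vector$name, "' collides with a host sequence name",
         call. = FALSE)
  }
  vg <- Biostrings::DNAStringSet(stats::setNames(vector$sequence, vector$name))
  structure(list(genome = c(host, vg), vector_names = vector$name),
            class = "aav_hybrid_ref")
}

#' @export
print.aav_hybrid_ref <- function(x, ...) {
  cat("<aav_hybrid_ref> ", length(x$genome), " sequences (",
      sum(!(names(x$genome) %in% x$vector_names)), " host + ",
      length(x$vector_names), " vector), total ",
      sum(Biostrings::width(x$genome)), " nt\n", sep = "")
  invisible(x)
}

#' Build a junction-validation reference
#'
#' Models the locus of a single integration: host flank, vector cassette,
#' host flank, as one sequence.  Used to visually validate a called junction
#' against supporting reads, mirroring the +/- flank chimeric reference a
#' genome browser would load.  Insertion is modelled without host loss by
#' default; `host_deletion` removes that many host bases at the junction.
#'
#' @param host Host genome.
#' @param vector An `aav_vector`.
#' @param chrom Host chromosome name.
#' @param pos1 1-based host coordinate of the insertion point: the cassette is
#'   inserted immediately after the base at `pos1` (the same convention
#'   [plant_integration()] uses).
#' @param flank Flank length on each side (default 5000); clipped at
#'   chromosome ends.
#' @param host_deletion Host bases deleted at the junction (default 0).
#' @return Single-sequence genome named `<chrom>:<pos1>:<vector name>`.
#' @export
build_validation_reference <- function(host, vector, chrom, pos1,
                                       flank = 5000, host_deletion = 0) {
  host <- as_genome(host)
  stopifnot(inherits(vector, "aav_vector"), flank >= 0, host_deletion >= 0)
  if (!chrom %in% names(host)) stop("chromosome '", chrom, "' not in host", call. = FALSE)
  L <- Biostrings::width(host)[match(chrom, names(host))]
  if (pos1 < 1 || pos1 > L) stop("pos1 out of range for ", chrom, call. = FALSE)
  s <- as.character(host[[chrom]])
  left <- substr(s, max(1, pos1 - flank + 1), pos1)
  right_from <- pos1 + host_deletion + 1
  right <- if (right_from > L) "" else substr(s, right_from, min(L, right_from + flank - 1))
  out <- paste0(left, vector$sequence, right)
  as_genome(stats::setNames(out, paste(chrom, pos1, vector$name, sep = ":")))
}

#' Tile capture probes across a vector target
#'
#' Tiles fixed-length probes at a fixed step across a target interval of the
#' vector, the design used for hybridization-capture enrichment of
#' vector-containing fragments.  With the defaults (120-nt probes, 40-nt
#' step) a full-length 2928-bp ITR-to-ITR cassette yields 71 probes.
#'
#' @param vector An `aav_vector`, or an integer target length.
#' @param target Optional 0-based half-open `c(start, end)` interval on the
#'   vector; defaults to the full sequence.
#' @param probe_len Probe length in nt (default 120).
#' @param step Tiling step in nt (default 40; the vendor's exact overlap is
#'   not published, 40 reproduces the printed probe count).
#' @return Tibble with columns `probe_id`, `start0`, `end0`, `start1`, `end1`
#'   and, when a vector sequence is available, `sequence`.
#' @export
#' @examples
#' nrow(design_capture_probes(2928L))  # 71
design_capture_probes <- function(vector, target = NULL, probe_len = 120, step = 40) {
  stopifnot(step >= 1, probe_len >= 1)
  seq <- NULL
  if (inherits(vector, "aav_vector")) {
    seq <- vector$sequence
    L <- nchar(seq)
  } else {
    L <- as.integer(vector)
  }
  if (is.null(target)) target <- c(0L, L)
  stopifnot(length(target) == 2, target[1] >= 0, target[2] <= L, target[1] < target[2])
  tlen <- target[2] - target[1]
  if (probe_len > tlen) stop("probe_len exceeds target length", call. = FALSE)
  n <- (tlen - probe_len) %/% step + 1L
  start0 <- target[1] + step * (seq_len(n) - 1L)
  out <- tibble::tibble(
    probe_id = sprintf("probe_%03d", seq_len(n)),
    start0 = as.integer(start0),
    end0 = as.integer(start0 + probe_len),
    start1 = as.integer(start0 + 1L),
    end1 = as.integer(start0 + probe_len)
  )
  if (!is.null(seq)) out$sequence <- substring(seq, out$start1, out$end1)
  out
}
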