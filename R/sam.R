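#' Import alignment blocks from SAM/BAM
#'
#' Converts primary and supplementary records of a SAM or BAM file into
#' alignment blocks.  Read coordinates are recovered from the clip lengths
#' and reported on the forward-oriented read (hard clips are treated like
#' soft clips for this arithmetic).  Matched-base counts use the MD tag when
#' present; otherwise NM, whose count includes indel bases, is decomposed
#' using the CIGAR indel lengths; with neither tag, matches fall back to the
#' aligned length and the block is flagged approximate via `source = "sam*"`.
#'
#' @param path SAM or BAM file.
#' @param ref Optional `aav_hybrid_ref` used to set `is_vector`.
#' @return Blocks tibble (see [align_reads()] for the schema).  Unmapped
#'   records are skipped; records without a CIGAR are rejected with a
#'   warning reporting the count.
#' @export
parse_sam_blocks <- function(path, ref = NULL) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar"),
    tag = c("NM", "MD")
  )
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(x$qname)
  if (n == 0) return(empty_blocks())

  mapped <- !bitwAnd(x$flag, 4L)
  has_cigar <- !is.na(x$cigar) & nzchar(x$cigar) & x$cigar != "*"
  n_rej <- sum(mapped & !has_cigar)
  if (n_rej > 0) warning(n_rej, " mapped record(s) without CIGAR rejected")
  use <- which(mapped & has_cigar)
  if (!length(use)) return(empty_blocks())

  md_all <- x$tag$MD
  if (is.null(md_all)) md_all <- rep(NA_character_, n)
  nm_all <- x$tag$NM
  if (is.null(nm_all)) nm_all <- rep(NA_integer_, n)

  rows <- purrr::map_dfr(use, function(i) {
    cg <- cigar_table(x$cigar[i])
    lead <- 0L; trail <- 0L
    clip <- cg$op %in% c("S", "H")
    if (nrow(cg) && clip[1]) lead <- cg$len[1]
    if (nrow(cg) > 1 && clip[nrow(cg)]) trail <- cg$len[nrow(cg)]
    q_aln <- sum(cg$len[cg$op %in% c("M", "I", "=", "X")])
    m_bases <- sum(cg$len[cg$op %in% c("M", "=", "X")])
    ins_b <- sum(cg$len[cg$op == "I"])
    del_b <- sum(cg$len[cg$op %in% c("D", "N")])
    ref_span <- m_bases + del_b
    read_len <- lead + trail + q_aln
    rev <- bitwAnd(x$flag[i], 16L) > 0
    rs <- if (rev) read_len - lead - q_aln else lead
    md <- md_all[i]
    nm <- nm_all[i]
    if (!is.na(md)) {
      matches <- sum(as.integer(unlist(regmatches(md, gregexpr("[0-9]+", md)))))
      src <- "sam"
    } else if (!is.na(nm)) {
      mism <- max(0L, nm - ins_b - del_b)
      matches <- m_bases - mism
      src <- "sam"
    } else {
      matches <- m_bases
      src <- "sam*"
    }
    tibble::tibble(
      read_id = x$qname[i], read_len = read_len,
      read_start = rs, read_end = rs + q_aln,
      strand = if (rev) "-" else "+",
      ref_name = as.character(x$rname[i]),
      ref_start = x$pos[i] - 1, ref_end = x$pos[i] - 1 + ref_span,
      matches = as.integer(matches), aligned_span = as.integer(q_aln),
      score = NA_integer_, source = src
    )
  })
  rows <- dplyr::filter(rows, .data$matches > 0)
  rows$match_score <- rows$matches / rows$aligned_span
  rows$is_vector <- if (!is.null(ref)) rows$ref_name %in% ref$vector_names else FALSE
  dplyr::arrange(
    dplyr::select(rows, dplyr::all_of(names(empty_blocks()))),
    .data$read_id, .data$read_start)
}

cigar_table <- function(cigar) {
  m <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  tibble::tibble(
    len = as.integer(sub("[MIDNSHP=X]$", "", m)),
    op = sub("^[0-9]+", "", m)
  )
}

empty_blocks <- function() {
  tibble::tibble(
    read_id = character(), read_len = integer(),
    read_start = integer(), read_end = integer(), strand = character(),
    ref_name = character(), ref_start = double(), ref_end = double(),
    matches = integer(), aligned_span = integer(), score = integer(),
    match_score = double(), source = character(), is_vector = logical()
  )
}
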