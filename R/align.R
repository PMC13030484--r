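#' Match score of alignment blocks
#'
#' The proportion of matched bases relative to the aligned span of the block,
#' the per-block statistic the short-read filters act on.
#'
#' @param matches Matched-base counts (or a blocks tibble; see Details).
#' @param aligned_span Read bases consumed by each block.
#' @return Numeric fractions in (0, 1].
#' @details When `matches` is a data frame with `matches` and `aligned_span`
#'   columns, the ratio is computed row-wise and returned as a vector.
#' @export
#' @examples
#' match_score(90, 100)
match_score <- function(matches, aligned_span = NULL) {
  if (is.data.frame(matches)) {
    aligned_span <- matches$aligned_span
    matches <- matches$matches
  }
  stopifnot(all(matches > 0), all(matches <= aligned_span))
  matches / aligned_span
}

default_k <- function(mode) if (mode == "short") 11L else 15L

#' Align reads against a hybrid reference
#'
#' Desk-scale seed-and-extend aligner: exact k-mer seeds on both strands,
#' chained by diagonal, each chain refined with a banded local alignment
#' (match +1, mismatch -2, gap base -3; log-phase scoring, so random
#' sequence cannot accumulate positive score).  One maximal block per chain is
#' kept when it reaches `min_block` read bases and a local alignment score of
#' `min_score` (a BLAT-style minimum output score).  Read coordinates are
#' reported on the forward-oriented read, so junction adjacency logic
#' downstream is strand-free.  Blocks duplicated by ITR palindromes are
#' reduced with [reduce_blocks()].
#'
#' @param reads Named `DNAStringSet` or named character vector.
#' @param ref An `aav_hybrid_ref` (or any genome; then `is_vector` is FALSE).
#' @param mode "long" (k = 15) or "short" (k = 11); `k` overrides.
#' @param k Seed length.
#' @param min_block Minimum block length on the read (default 30 nt, below
#'   the callers' own thresholds so filtering stays their decision).
#' @param min_score Minimum local-alignment score (default 30).
#' @param band Half-width of the alignment band around the seed diagonal;
#'   defaults to 100 for long reads (nanopore-scale indel drift) and 20 for
#'   short reads.
#' @param reduce Apply [reduce_blocks()] (default TRUE).
#' @return Tibble of alignment blocks: `read_id`, `read_len`, `read_start`,
#'   `read_end` (0-based half-open, forward-oriented read), `strand`,
#'   `ref_name`, `ref_start`, `ref_end` (0-based half-open), `matches`,
#'   `aligned_span`, `score`, `match_score`, `source`, `is_vector`.
#' @export
align_reads <- function(reads, ref, mode = c("long", "short"), k = NULL,
                        min_block = 30L, min_score = 30L, band = NULL,
                        reduce = TRUE) {
  mode <- match.arg(mode)
  if (is.null(k)) k <- default_k(mode)
  if (is.null(band)) band <- if (mode == "short") 20L else 100L
  if (methods::is(reads, "DNAStringSet")) reads <- as.character(reads)
  if (is.null(names(reads)) || any(!nzchar(names(reads))))
    stop("reads must be named", call. = FALSE)
  genome <- if (inherits(ref, "aav_hybrid_ref")) ref$genome else as_genome(ref)
  vec_names <- if (inherits(ref, "aav_hybrid_ref")) ref$vector_names else character()

  df <- cpp_se_align(names(reads), unname(toupper(reads)),
                     names(genome), as.character(genome),
                     as.integer(k), as.integer(min_block), as.integer(min_score),
                     as.integer(band), 50L, 50L, 64L)
  blocks <- tibble::as_tibble(df) %>%
    dplyr::mutate(match_score = .data$matches / .data$aligned_span,
                  source = "internal",
                  is_vector = .data$ref_name %in% vec_names)
  if (reduce) blocks <- reduce_blocks(blocks)
  dplyr::arrange(blocks, .data$read_id, .data$read_start)
}

#' Reduce redundant blocks on a read
#'
#' ITR palindromes routinely give one read segment two near-identical vector
#' alignments.  Within each read, blocks overlapping a better block by more
#' than `max_overlap` of the shorter block's span are dropped; "better" is
#' more matches, then longer reference span, then lexicographic reference
#' name and coordinate.
#'
#' @param blocks Blocks tibble.
#' @param max_overlap Maximal tolerated mutual overlap fraction (default 0.5).
#' @return Filtered blocks tibble.
#' @export
reduce_blocks <- function(blocks, max_overlap = 0.5) {
  if (nrow(blocks) == 0) return(blocks)
  multi <- blocks$read_id %in% blocks$read_id[duplicated(blocks$read_id)]
  if (!any(multi)) return(blocks)
  dplyr::bind_rows(blocks[!multi, , drop = FALSE], blocks[multi, , drop = FALSE] %>%
    dplyr::group_by(.data$read_id) %>%
    dplyr::group_modify(function(d, g) {
      ord <- order(-d$matches, -(d$ref_end - d$ref_start), d$ref_name, d$ref_start)
      keep <- logical(nrow(d))
      for (i in ord) {
        ok <- TRUE
        for (j in which(keep)) {
          ov <- min(d$read_end[i], d$read_end[j]) - max(d$read_start[i], d$read_start[j])
          if (ov > max_overlap * min(d$aligned_span[i], d$aligned_span[j])) { ok <- FALSE; break }
        }
        keep[i] <- ok
      }
      d[keep, , drop = FALSE]
    }) %>%
    dplyr::ungroup())
}

#' Flag vector-derived blocks
#'
#' @param blocks Blocks tibble.
#' @param ref An `aav_hybrid_ref`.
#' @return Blocks with the `is_vector` column set from the reference.
#' @export
flag_vector_blocks <- function(blocks, ref) {
  stopifnot(inherits(ref, "aav_hybrid_ref"))
  dplyr::mutate(blocks, is_vector = .data$ref_name %in% ref$vector_names)
}

block_cols <- readr::cols(
  read_id = readr::col_character(),
  read_len = readr::col_integer(),
  read_start = readr::col_integer(),
  read_end = readr::col_integer(),
  strand = readr::col_character(),
  ref_name = readr::col_character(),
  ref_start = readr::col_double(),
  ref_end = readr::col_double(),
  matches = readr::col_integer(),
  aligned_span = readr::col_integer(),
  score = readr::col_integer(),
  match_score = readr::col_double(),
  source = readr::col_character(),
  is_vector = readr::col_logical()
)

#' Read/write alignment blocks as TSV
#'
#' Round-trips the block table byte-exactly (comment lines starting with
#' `#` are skipped on read, so provenance headers survive).
#'
#' @param blocks Blocks tibble.
#' @param path File path.
#' @param header Optional character vector of `#`-prefixed comment lines.
#' @export
write_blocks <- function(blocks, path, header = NULL) {
  if (!is.null(header)) {
    readr::write_lines(header, path)
    readr::write_tsv(blocks, path, append = TRUE, col_names = TRUE)
  } else {
    readr::write_tsv(blocks, path)
  }
  invisible(path)
}

#' @rdname write_blocks
#' @export
read_blocks <- function(path) {
  readr::read_tsv(path, comment = "#", col_types = block_cols, progress = FALSE)
}
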