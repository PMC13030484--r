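#' Extract chimeric candidate block pairs
#'
#' For each read carrying at least one vector and one host block, emits the
#' host/vector block pairs that are adjacent on the (forward-oriented) read.
#' Reads aligning to only one reference class emit nothing.  A per-read
#' `collinear` flag records whether multiple blocks on the same reference
#' share strand and run in read order (its violation marks a mapping
#' artifact and is enforced by [check_consistency()]).
#'
#' @param blocks Blocks tibble with `is_vector` set (see [align_reads()],
#'   [flag_vector_blocks()]).
#' @return Tibble of candidate pairs, one row per adjacent host/vector block
#'   pair, with `host_*` and `vector_*` block columns, `vector_first`, and
#'   `gap` (signed read-coordinate gap; negative = overlap).
#' @export
extract_chimeric_candidates <- function(blocks) {
  if (nrow(blocks) > 0) {
    mixed <- intersect(blocks$read_id[blocks$is_vector],
                       blocks$read_id[!blocks$is_vector])
    blocks <- blocks[blocks$read_id %in% mixed, , drop = FALSE]
  }
  if (nrow(blocks) == 0) return(empty_pairs())
  blocks %>%
    dplyr::group_by(.data$read_id) %>%
    dplyr::group_modify(function(d, g) {
      if (!any(d$is_vector) || !any(!d$is_vector)) return(empty_pairs()[, -1])
      d <- d[order(d$read_start, d$read_end), , drop = FALSE]
      coll <- read_collinear(d)
      idx <- which(d$is_vector[-nrow(d)] != d$is_vector[-1])
      if (!length(idx)) return(empty_pairs()[, -1])
      purrr::map_dfr(idx, function(i) {
        up <- d[i, ]; down <- d[i + 1, ]
        h <- if (up$is_vector) down else up
        v <- if (up$is_vector) up else down
        tibble::tibble(
          vector_first = up$is_vector,
          gap = down$read_start - up$read_end,
          collinear = coll,
          host_read_start = h$read_start, host_read_end = h$read_end,
          host_strand = h$strand, host_ref = h$ref_name,
          host_ref_start = h$ref_start, host_ref_end = h$ref_end,
          host_matches = h$matches, host_span = h$aligned_span,
          host_score = h$match_score,
          vector_read_start = v$read_start, vector_read_end = v$read_end,
          vector_block_strand = v$strand, vector_ref = v$ref_name,
          vector_ref_start = v$ref_start, vector_ref_end = v$ref_end,
          vector_matches = v$matches, vector_span = v$aligned_span,
          vector_score = v$match_score
        )
      })
    }) %>%
    dplyr::ungroup()
}

# blocks of one read, in read order: multiple blocks on one reference must
# share strand and advance monotonically along it
read_collinear <- function(d) {
  for (rn in unique(d$ref_name[duplicated(d$ref_name)])) {
    e <- d[d$ref_name == rn, , drop = FALSE]
    if (length(unique(e$strand)) > 1) return(FALSE)
    dd <- diff(e$ref_start)
    # tandem repeats (concatemers) legitimately revisit coordinates, so only
    # strictly opposing order on the read and reference axes is rejected
    if (length(dd)) {
      if (e$strand[1] == "+" && all(dd < 0)) return(FALSE)
      if (e$strand[1] == "-" && all(dd > 0)) return(FALSE)
    }
  }
  TRUE
}

empty_pairs <- function() {
  tibble::tibble(
    read_id = character(), vector_first = logical(), gap = integer(),
    collinear = logical(),
    host_read_start = integer(), host_read_end = integer(),
    host_strand = character(), host_ref = character(),
    host_ref_start = double(), host_ref_end = double(),
    host_matches = integer(), host_span = integer(), host_score = double(),
    vector_read_start = integer(), vector_read_end = integer(),
    vector_block_strand = character(), vector_ref = character(),
    vector_ref_start = double(), vector_ref_end = double(),
    vector_matches = integer(), vector_span = integer(), vector_score = double()
  )
}

#' Threshold filter on candidate pairs
#'
#' A pair is accepted when both its host and vector blocks exceed
#' `min_match_nt` matched bases (strict inequality) and both match scores
#' reach `min_score`.
#'
#' @param pairs Candidate pairs from [extract_chimeric_candidates()].
#' @param min_match_nt Matched-base threshold, strict `>` (default 35).
#' @param min_score Minimum match score (default 0.9).
#' @return `pairs` with logical `filter_pass` and character `filter_reason`
#'   columns.
#' @export
filter_pairs <- function(pairs, min_match_nt = 35, min_score = 0.9) {
  reason <- dplyr::case_when(
    pairs$host_matches <= min_match_nt ~ "host_matches",
    pairs$vector_matches <= min_match_nt ~ "vector_matches",
    pairs$host_score < min_score ~ "host_score",
    pairs$vector_score < min_score ~ "vector_score",
    TRUE ~ NA_character_
  )
  dplyr::mutate(pairs, filter_pass = is.na(reason), filter_reason = reason)
}

#' Proximity / orientation consistency filter
#'
#' Accepts pairs whose blocks sit within `window` nt of each other along the
#' read (|gap| <= window; overlaps count as microhomology-like and are
#' recorded, not rejected) and whose read shows collinear same-reference
#' alignments.
#'
#' @param pairs Pairs tibble (after [filter_pairs()]).
#' @param window Maximal |gap| in nt (default 20).
#' @return `pairs` with logical `consistency_pass` and `consistency_reason`.
#' @export
check_consistency <- function(pairs, window = 20) {
  reason <- dplyr::case_when(
    abs(pairs$gap) > window ~ "gap",
    !pairs$collinear ~ "collinearity",
    TRUE ~ NA_character_
  )
  dplyr::mutate(pairs, consistency_pass = is.na(reason),
                consistency_reason = reason)
}

#' Derive junction calls from accepted pairs
#'
#' The junction coordinate comes from the host block and depends on the
#' orientation of the vector segment on the read: with the vector segment
#' preceding the host block, the junction is the host block's read-upstream
#' reference boundary; with the vector following, its read-downstream
#' boundary.  Boundaries are converted to 1-based host forward-strand
#' coordinates using the host block strand; `side` reports on which side of
#' the coordinate the retained host flank lies.  The vector breakpoint is
#' derived from the vector block's junction-adjacent boundary the same way.
#'
#' @param pairs Pairs tibble; only rows passing both filters (when the
#'   columns are present) are used.
#' @return Tibble of junction calls: `read_id`, `chrom`, `pos1`, `side`,
#'   `vector_pos1`, `vector_strand`, `human_score`, `vector_score`, `gap`.
#' @export
derive_junctions <- function(pairs) {
  if ("filter_pass" %in% names(pairs)) pairs <- dplyr::filter(pairs, .data$filter_pass)
  if ("consistency_pass" %in% names(pairs)) pairs <- dplyr::filter(pairs, .data$consistency_pass)
  if (nrow(pairs) == 0) {
    return(tibble::tibble(read_id = character(), chrom = character(),
                          pos1 = double(), side = character(),
                          vector_pos1 = double(), vector_strand = character(),
                          human_score = double(), vector_score = double(),
                          gap = integer()))
  }
  host_plus <- pairs$host_strand == "+"
  upstream_boundary <- ifelse(host_plus, pairs$host_ref_start + 1, pairs$host_ref_end)
  downstream_boundary <- ifelse(host_plus, pairs$host_ref_end, pairs$host_ref_start + 1)
  pos1 <- ifelse(pairs$vector_first, upstream_boundary, downstream_boundary)
  side <- ifelse(pairs$vector_first,
                 ifelse(host_plus, "right", "left"),
                 ifelse(host_plus, "left", "right"))
  vec_plus <- pairs$vector_block_strand == "+"
  vector_pos1 <- ifelse(pairs$vector_first,
                        ifelse(vec_plus, pairs$vector_ref_end, pairs$vector_ref_start + 1),
                        ifelse(vec_plus, pairs$vector_ref_start + 1, pairs$vector_ref_end))
  tibble::tibble(
    read_id = pairs$read_id,
    chrom = pairs$host_ref,
    pos1 = pos1,
    side = side,
    vector_pos1 = vector_pos1,
    vector_strand = ifelse(pairs$host_strand == pairs$vector_block_strand, "+", "-"),
    human_score = pairs$host_score,
    vector_score = pairs$vector_score,
    gap = pairs$gap
  )
}

#' Aggregate junction calls per coordinate
#'
#' Groups calls by unique (chrom, pos1, side), counting distinct supporting
#' reads, sorted by support (descending) then coordinate.
#'
#' @param calls Junction calls from [derive_junctions()].
#' @return Summary tibble (`chrom`, `pos1`, `side`, `support`, `read_ids`
#'   semicolon-joined) of class `aav_summary`.
#' @export
aggregate_junctions <- function(calls) {
  out <- calls %>%
    dplyr::group_by(.data$chrom, .data$pos1, .data$side) %>%
    dplyr::summarise(support = dplyr::n_distinct(.data$read_id),
                     read_ids = paste(sort(unique(.data$read_id)), collapse = ";"),
                     .groups = "drop") %>%
    dplyr::arrange(dplyr::desc(.data$support), .data$chrom, .data$pos1)
  class(out) <- c("aav_summary", class(out))
  out
}
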