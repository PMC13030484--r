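#' Derive breakend adjacencies from split long-read alignments
#'
#' For each read with two or more blocks (after overlap reduction), emits one
#' breakend pair per consecutive block pair on the forward-oriented read.
#' Breakend positions are the junction-adjacent reference boundaries with
#' strand-corrected sides ("end" = the segment continues to lower reference
#' coordinates, "start" = to higher), 1-based; `read_gap` is the signed
#' read-coordinate gap between the blocks.
#'
#' @param blocks Blocks tibble with `is_vector` set.
#' @return Tibble of breakend pairs: `read_id`, `refA`, `posA`, `sideA`,
#'   `strandA`, `is_vectorA`, the same for B, and `read_gap`.  Single-block
#'   reads emit nothing.
#' @export
derive_adjacencies <- function(blocks) {
  multi <- blocks$read_id %in% blocks$read_id[duplicated(blocks$read_id)]
  blocks <- blocks[multi, , drop = FALSE]
  if (nrow(blocks) == 0) return(empty_adjacencies())
  blocks %>%
    dplyr::group_by(.data$read_id) %>%
    dplyr::group_modify(function(d, g) {
      if (nrow(d) < 2) return(empty_adjacencies()[, -1])
      d <- d[order(d$read_start, d$read_end), , drop = FALSE]
      purrr::map_dfr(seq_len(nrow(d) - 1), function(i) {
        a <- d[i, ]; b <- d[i + 1, ]
        a_plus <- a$strand == "+"
        b_plus <- b$strand == "+"
        tibble::tibble(
          refA = a$ref_name,
          posA = ifelse(a_plus, a$ref_end, a$ref_start + 1),
          sideA = ifelse(a_plus, "end", "start"),
          strandA = a$strand, is_vectorA = a$is_vector,
          refB = b$ref_name,
          posB = ifelse(b_plus, b$ref_start + 1, b$ref_end),
          sideB = ifelse(b_plus, "start", "end"),
          strandB = b$strand, is_vectorB = b$is_vector,
          read_gap = b$read_start - a$read_end
        )
      })
    }) %>%
    dplyr::ungroup()
}

empty_adjacencies <- function() {
  tibble::tibble(
    read_id = character(), refA = character(), posA = double(),
    sideA = character(), strandA = character(), is_vectorA = logical(),
    refB = character(), posB = double(), sideB = character(),
    strandB = character(), is_vectorB = logical(), read_gap = integer()
  )
}

#' Select vector-host breakend pairs
#'
#' Keeps exactly the adjacencies joining one vector-side and one host-side
#' breakend, within the read-gap window, and normalises them so the host
#' breakend carries the event coordinate.  The host `side` is reported as
#' "left"/"right": the side of the coordinate on which the retained host
#' flank lies on the forward strand.  Vector-vector adjacencies (concatemer
#' internal junctions) are dropped here and handled by
#' [reconstruct_vector_structure()].
#'
#' @param pairs Breakend pairs from [derive_adjacencies()].
#' @param window Maximal |read_gap| in nt (default 50 for long reads).
#' @return Tibble: `read_id`, `chrom`, `pos1`, `side`, `vector_pos1`,
#'   `vector_strand`, `read_gap`.
#' @export
select_vector_host <- function(pairs, window = 50) {
  keep <- xor(pairs$is_vectorA, pairs$is_vectorB) & abs(pairs$read_gap) <= window
  p <- pairs[keep, , drop = FALSE]
  if (nrow(p) == 0) {
    return(tibble::tibble(read_id = character(), chrom = character(),
                          pos1 = double(), side = character(),
                          vector_pos1 = double(), vector_strand = character(),
                          read_gap = integer()))
  }
  host_is_A <- !p$is_vectorA
  tibble::tibble(
    read_id = p$read_id,
    chrom = ifelse(host_is_A, p$refA, p$refB),
    pos1 = ifelse(host_is_A, p$posA, p$posB),
    side = ifelse(ifelse(host_is_A, p$sideA, p$sideB) == "end", "left", "right"),
    vector_pos1 = ifelse(host_is_A, p$posB, p$posA),
    vector_strand = ifelse(p$strandA == p$strandB, "+", "-"),
    read_gap = p$read_gap
  )
}

#' Cluster vector-host breakends into integration events
#'
#' Single-linkage clustering of host-side positions within each
#' (chrom, side) at linkage distance `tol`; the representative event
#' coordinate is the member median (lower of the two middles for even
#' counts), robust to long-read end jitter.
#'
#' @param pairs Selected pairs from [select_vector_host()].
#' @param tol Linkage distance in nt (default 25).
#' @param min_support Minimum distinct supporting reads to report an event.
#' @return Tibble of class `aav_events`: `chrom`, `pos1`, `side`, `support`,
#'   `read_names` (list), `vector_pos1` (median), `is_baseline` (FALSE here;
#'   see [rank_baseline()]), `member_positions` (list).
#' @export
cluster_events <- function(pairs, tol = 25, min_support = 1) {
  if (nrow(pairs) == 0) {
    out <- tibble::tibble(chrom = character(), pos1 = double(), side = character(),
                          support = integer(), read_names = list(),
                          vector_pos1 = double(), is_baseline = logical(),
                          member_positions = list())
    class(out) <- c("aav_events", class(out))
    return(out)
  }
  out <- pairs %>%
    dplyr::arrange(.data$chrom, .data$side, .data$pos1) %>%
    dplyr::group_by(.data$chrom, .data$side) %>%
    dplyr::group_modify(function(d, g) {
      brk <- c(0, cumsum(diff(d$pos1) > tol))
      d$cluster <- brk
      d %>%
        dplyr::group_by(.data$cluster) %>%
        dplyr::summarise(
          member_positions = list(.data$pos1),
          support = dplyr::n_distinct(.data$read_id),
          read_names = list(sort(unique(.data$read_id))),
          vector_pos1 = lower_median(.data$vector_pos1),
          pos1 = lower_median(member_positions[[1]]),
          .groups = "drop") %>%
        dplyr::select(-"cluster")
    }) %>%
    dplyr::ungroup() %>%
    dplyr::mutate(is_baseline = FALSE) %>%
    dplyr::filter(.data$support >= min_support) %>%
    dplyr::select("chrom", "pos1", "side", "support", "read_names",
                  "vector_pos1", "is_baseline", "member_positions") %>%
    dplyr::arrange(dplyr::desc(.data$support), .data$chrom, .data$pos1)
  class(out) <- c("aav_events", class(out))
  out
}

# median taking the lower of the two middle values for even counts
lower_median <- function(x) sort(x)[ceiling(length(x) / 2)]

#' Designate the baseline integration site
#'
#' Flags the single event with the highest supporting-read count as the
#' clone's baseline integration site; ties break toward the tighter cluster
#' (smaller member-position spread), then lexicographic (chrom, pos1).
#'
#' @param events Events from [cluster_events()].
#' @return `events` with exactly one `is_baseline = TRUE` row (none for an
#'   empty event set, with a warning).
#' @export
rank_baseline <- function(events) {
  if (nrow(events) == 0) {
    warning("no events; no baseline designated")
    return(events)
  }
  spread <- vapply(events$member_positions,
                   function(p) diff(range(p)), numeric(1))
  ord <- order(-events$support, spread, events$chrom, events$pos1)
  events$is_baseline <- FALSE
  events$is_baseline[ord[1]] <- TRUE
  events
}

#' Reconstruct the local vector structure of each read
#'
#' Orders each read's vector blocks along the read and classifies adjacent
#' block relations on the vector: a reference gap > `gap_tol` nt is an
#' internal deletion, a reference overlap > `gap_tol` nt a
#' duplication/rearrangement (a full-length overlap being a head-to-tail
#' concatemer junction), and mixed orientations an inversion.  Host-vector
#' junction read gaps are reported as junction indels.
#'
#' @param blocks Blocks tibble with `is_vector` set (all reads at once).
#' @param vector_length Vector sequence length, to label full-length covers.
#' @param gap_tol Alteration size threshold in nt (default 30).
#' @return Tibble, one row per read with a vector block: `read_id`, `label`
#'   ("full_length", "partial", or semicolon-joined alteration types),
#'   `n_segments`, `segments` (list of tibbles with `start0`, `end0`,
#'   `orient`), `alterations` (list of tibbles with `type`, `size`),
#'   `junction_gaps` (list of host-vector read gaps).
#' @export
reconstruct_vector_structure <- function(blocks, vector_length, gap_tol = 30) {
  stopifnot(nrow(blocks) == 0 || "is_vector" %in% names(blocks))
  reads <- unique(blocks$read_id[blocks$is_vector])
  purrr::map_dfr(reads, function(rid) {
    d <- blocks[blocks$read_id == rid, , drop = FALSE]
    d <- d[order(d$read_start), , drop = FALSE]
    v <- d[d$is_vector, , drop = FALSE]
    segs <- tibble::tibble(start0 = v$ref_start, end0 = v$ref_end, orient = v$strand)
    alt <- tibble::tibble(type = character(), size = double())
    if (nrow(v) > 1) {
      for (i in seq_len(nrow(v) - 1)) {
        a <- v[i, ]; b <- v[i + 1, ]
        if (a$strand != b$strand) {
          alt <- dplyr::bind_rows(alt, tibble::tibble(type = "inversion", size = NA_real_))
          next
        }
        gap <- if (a$strand == "+") b$ref_start - a$ref_end else a$ref_start - b$ref_end
        if (gap > gap_tol) {
          alt <- dplyr::bind_rows(alt, tibble::tibble(type = "deletion", size = gap))
        } else if (-gap > gap_tol) {
          alt <- dplyr::bind_rows(alt, tibble::tibble(type = "duplication", size = -gap))
        }
      }
    }
    # read gaps at host-vector junctions (junction indel sizes)
    jgaps <- integer()
    if (nrow(d) > 1) {
      for (i in seq_len(nrow(d) - 1)) {
        if (xor(d$is_vector[i], d$is_vector[i + 1])) {
          jgaps <- c(jgaps, d$read_start[i + 1] - d$read_end[i])
        }
      }
    }
    covered <- sum(segs$end0 - segs$start0)
    label <- if (nrow(alt)) {
      paste(unique(alt$type), collapse = ";")
    } else if (nrow(segs) >= 1 && covered >= vector_length - gap_tol &&
               nrow(segs) == 1) {
      "full_length"
    } else {
      "partial"
    }
    tibble::tibble(read_id = rid, label = label, n_segments = nrow(segs),
                   segments = list(segs), alterations = list(alt),
                   junction_gaps = list(jgaps))
  })
}
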