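#' Caller configuration
#'
#' Tunable parameters of both junction-calling workflows, with the package
#' defaults: seed k-mers of 15 nt (long) / 11 nt (short); minimum block span
#' and local-alignment score of 30; the short-read matched-base threshold of
#' >35 nt with a 0.9 match score; read-coordinate proximity windows of 20 nt
#' (short) / 50 nt (long); 25-nt single-linkage clustering.
#'
#' @param ... Overrides for any of: `k_long`, `k_short`, `min_block`,
#'   `min_align_score`, `band_long`, `band_short`, `min_match_nt`,
#'   `min_score`, `window_short`, `window_long`, `tol`, `min_support`.
#' @return Named list of class `aav_call_config`.
#' @export
call_config <- function(...) {
  cfg <- modifyList(list(
    k_long = 15L, k_short = 11L, min_block = 30L, min_align_score = 30L,
    band_long = 100L, band_short = 20L, min_match_nt = 35, min_score = 0.9,
    window_short = 20, window_long = 50, tol = 25, min_support = 1L
  ), list(...))
  structure(cfg, class = "aav_call_config")
}

#' Long-read junction-calling pipeline
#'
#' Runs the full long-read workflow: align reads to the hybrid reference,
#' derive breakend adjacencies from split alignments, select vector-host
#' pairs, cluster them into integration events, and designate the baseline
#' site.  Deterministic for fixed inputs.
#'
#' @param reads Named `DNAStringSet` / named character vector, or a FASTQ
#'   path.
#' @param ref An `aav_hybrid_ref`.
#' @param config An `aav_call_config`.
#' @param blocks Optional precomputed blocks tibble (e.g. from
#'   [parse_sam_blocks()]); skips the internal aligner.
#' @param verbose Log per-stage counts to stderr.
#' @return List of class `aav_long_result`: `events` (tibble with baseline
#'   flag), `structures` (per-read vector structure), `pairs`, `blocks`,
#'   `stages` (per-stage counts).
#' @export
run_long_pipeline <- function(reads = NULL, ref, config = call_config(),
                              blocks = NULL, verbose = TRUE) {
  if (!is.null(reads) && is.character(reads) && length(reads) == 1 &&
      file.exists(reads)) {
    reads <- read_fastq(reads)
  }
  if (is.null(blocks)) {
    if (length(reads) == 0) {
      warning("no reads; returning empty events")
      blocks <- empty_blocks()
    } else {
      blocks <- align_reads(reads, ref, mode = "long", k = config$k_long,
                            min_block = config$min_block,
                            min_score = config$min_align_score,
                            band = config$band_long)
    }
  } else {
    blocks <- flag_vector_blocks(reduce_blocks(blocks), ref)
  }
  adj <- derive_adjacencies(blocks)
  sel <- select_vector_host(adj, window = config$window_long)
  events <- cluster_events(sel, tol = config$tol,
                           min_support = config$min_support)
  if (nrow(events) > 0) events <- rank_baseline(events)
  vlen <- max(c(0, Biostrings::width(ref$genome)[names(ref$genome) %in% ref$vector_names]))
  structures <- reconstruct_vector_structure(blocks, vector_length = vlen)
  stages <- stage_counts(
    reads = if (!is.null(reads)) length(reads) else NA_integer_,
    aligned_reads = dplyr::n_distinct(blocks$read_id),
    adjacencies = nrow(adj),
    vector_host_pairs = nrow(sel),
    events = nrow(events)
  )
  aj_log("long pipeline: ", paste(stages$stage, stages$n, sep = "=", collapse = ", "),
         verbose = verbose)
  structure(list(events = events, structures = structures, pairs = sel,
                 blocks = blocks, stages = stages),
            class = "aav_long_result")
}

#' Short-read junction-calling pipeline
#'
#' Runs the full short-read workflow: align each mate to the hybrid
#' reference, extract host/vector block pairs adjacent on the read, apply
#' the matched-base (> `min_match_nt`) and match-score filters and the
#' proximity/collinearity consistency check, derive orientation-dependent
#' junction coordinates, and aggregate per-coordinate support.
#'
#' @param r1 R1 reads (named `DNAStringSet`/character, or FASTQ path).
#' @param r2 Optional R2 reads; ignored when `r1_only = TRUE`.
#' @param ref An `aav_hybrid_ref`.
#' @param config An `aav_call_config`.
#' @param r1_only Process only R1 (the upstream workflow this reproduces
#'   retrieved candidate sequences from the R1 FASTQ only).
#' @param blocks Optional precomputed blocks tibble (e.g. from
#'   [parse_psl_blocks()]); skips the internal aligner.
#' @param verbose Log per-stage counts to stderr.
#' @return List of class `aav_short_result`: `summary` (per-coordinate
#'   support), `annotation` (read-level calls), `pairs`, `stages`.
#' @export
run_short_pipeline <- function(r1 = NULL, r2 = NULL, ref, config = call_config(),
                               r1_only = FALSE, blocks = NULL, verbose = TRUE) {
  if (is.null(blocks)) {
    if (is.character(r1) && length(r1) == 1 && file.exists(r1)) r1 <- read_fastq(r1)
    if (!is.null(r2) && is.character(r2) && length(r2) == 1 && file.exists(r2)) {
      r2 <- read_fastq(r2)
    }
    reads <- if (r1_only || is.null(r2)) r1 else c(r1, r2)
    if (length(reads) == 0) {
      warning("no reads; returning empty summary")
      blocks <- empty_blocks()
    } else {
      blocks <- align_reads(reads, ref, mode = "short", k = config$k_short,
                            min_block = config$min_block,
                            min_score = config$min_align_score,
                            band = config$band_short)
    }
  } else {
    blocks <- flag_vector_blocks(reduce_blocks(blocks), ref)
  }
  cand <- extract_chimeric_candidates(blocks)
  filt <- filter_pairs(cand, min_match_nt = config$min_match_nt,
                       min_score = config$min_score)
  cons <- check_consistency(filt, window = config$window_short)
  calls <- derive_junctions(cons)
  summary <- aggregate_junctions(calls)
  stages <- stage_counts(
    aligned_reads = dplyr::n_distinct(blocks$read_id),
    candidates = nrow(cand),
    after_threshold = sum(filt$filter_pass),
    after_consistency = sum(cons$filter_pass & cons$consistency_pass),
    calls = nrow(calls),
    unique_sites = nrow(summary)
  )
  rejects <- c(table(filt$filter_reason), table(cons$consistency_reason))
  aj_log("short pipeline: ",
         paste(stages$stage, stages$n, sep = "=", collapse = ", "),
         if (length(rejects)) paste0("; rejected: ",
                                     paste(names(rejects), rejects, sep = "=", collapse = ", ")),
         verbose = verbose)
  structure(list(summary = summary, annotation = calls, pairs = cons,
                 stages = stages),
            class = "aav_short_result")
}

#' @export
print.aav_long_result <- function(x, ...) {
  cat("<aav_long_result> ", nrow(x$events), " event(s)\n", sep = "")
  if (nrow(x$events)) print(tibble::as_tibble(x$events[, c("chrom", "pos1", "side",
                                                           "support", "is_baseline")]))
  invisible(x)
}

#' @export
print.aav_short_result <- function(x, ...) {
  cat("<aav_short_result> ", nrow(x$summary), " unique site(s)\n", sep = "")
  if (nrow(x$summary)) print(tibble::as_tibble(x$summary))
  invisible(x)
}

#' Cross-method concordance of two callsets
#'
#' Greedy nearest matching, per chromosome, of long-read events against
#' short-read summary rows within `tol` nt; unmatched rows are labelled
#' `long_only` / `short_only`.  Matching is symmetric in the two callsets up
#' to the status labels.
#'
#' @param long_events Tibble with `chrom`, `pos1` (e.g. `result$events`).
#' @param short_summary Tibble with `chrom`, `pos1`.
#' @param tol Matching tolerance in nt (default 10).
#' @return Tibble of class `aav_concordance`: `chrom`, `pos1_long`,
#'   `pos1_short`, `distance`, `status`.
#' @export
compare_callsets <- function(long_events, short_summary, tol = 10) {
  out <- purrr::map_dfr(
    union(unique(long_events$chrom), unique(short_summary$chrom)),
    function(cn) {
      lp <- sort(long_events$pos1[long_events$chrom == cn])
      sp <- sort(short_summary$pos1[short_summary$chrom == cn])
      cand <- expand.grid(i = seq_along(lp), j = seq_along(sp))
      if (nrow(cand)) {
        cand$d <- abs(lp[cand$i] - sp[cand$j])
        cand <- cand[cand$d <= tol, , drop = FALSE]
        cand <- cand[order(cand$d, cand$i, cand$j), , drop = FALSE]
      }
      used_i <- logical(length(lp)); used_j <- logical(length(sp))
      rows <- list()
      for (r in seq_len(nrow(cand))) {
        i <- cand$i[r]; j <- cand$j[r]
        if (used_i[i] || used_j[j]) next
        used_i[i] <- TRUE; used_j[j] <- TRUE
        rows[[length(rows) + 1]] <- tibble::tibble(
          chrom = cn, pos1_long = lp[i], pos1_short = sp[j],
          distance = cand$d[r], status = "both")
      }
      for (i in which(!used_i)) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          chrom = cn, pos1_long = lp[i], pos1_short = NA_real_,
          distance = NA_real_, status = "long_only")
      }
      for (j in which(!used_j)) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          chrom = cn, pos1_long = NA_real_, pos1_short = sp[j],
          distance = NA_real_, status = "short_only")
      }
      dplyr::bind_rows(rows)
    })
  out <- dplyr::arrange(out, .data$chrom,
                        dplyr::coalesce(.data$pos1_long, .data$pos1_short))
  class(out) <- c("aav_concordance", class(out))
  out
}

#' Evaluate calls against a simulation truth set
#'
#' Matches each call greedily (nearest first) to at most one truth junction
#' within `tol` nt on the same chromosome; precision is the matched fraction
#' of calls, recall the detected fraction of truth sites, and per-site
#' coordinate errors are reported.
#'
#' @param calls Tibble with `chrom`, `pos1` (events or summary rows).
#' @param truth Junction truth tibble (e.g. `clone$junctions`), optionally
#'   filtered to the sides of interest.
#' @param tol Matching tolerance in nt (default 10).
#' @return Object of class `aav_eval` with `sites` (per-truth-site tibble:
#'   detected flag, coordinate error), `n_calls`, `n_matched`, `precision`,
#'   `recall`.
#' @export
evaluate_against_truth <- function(calls, truth, tol = 10) {
  stopifnot(all(c("chrom", "pos1") %in% names(calls)),
            all(c("chrom", "pos1") %in% names(truth)))
  t_used <- logical(nrow(truth))
  c_matched <- logical(nrow(calls))
  err <- rep(NA_real_, nrow(truth))
  if (nrow(calls) && nrow(truth)) {
    cand <- expand.grid(ci = seq_len(nrow(calls)), ti = seq_len(nrow(truth)))
    cand$d <- abs(calls$pos1[cand$ci] - truth$pos1[cand$ti])
    cand <- cand[calls$chrom[cand$ci] == truth$chrom[cand$ti] & cand$d <= tol, ,
                 drop = FALSE]
    cand <- cand[order(cand$d, cand$ci, cand$ti), , drop = FALSE]
    for (r in seq_len(nrow(cand))) {
      ci <- cand$ci[r]; ti <- cand$ti[r]
      if (c_matched[ci] || t_used[ti]) next
      c_matched[ci] <- TRUE; t_used[ti] <- TRUE
      err[ti] <- cand$d[r]
    }
  }
  sites <- tibble::tibble(
    chrom = truth$chrom, pos1 = truth$pos1,
    side = if ("side" %in% names(truth)) truth$side else NA_character_,
    detected = t_used, coord_error = err
  )
  structure(list(
    sites = sites,
    n_calls = nrow(calls),
    n_matched = sum(c_matched),
    precision = if (nrow(calls)) sum(c_matched) / nrow(calls) else NA_real_,
    recall = if (nrow(truth)) mean(t_used) else NA_real_
  ), class = "aav_eval")
}

#' @export
print.aav_eval <- function(x, ...) {
  cat("<aav_eval> precision ", format(x$precision, digits = 3),
      ", recall ", format(x$recall, digits = 3),
      " (", x$n_matched, "/", x$n_calls, " calls matched)\n", sep = "")
  invisible(x)
}

#' Tidy an evaluation report
#'
#' @param x An `aav_eval`.
#' @param ... Unused.
#' @return `tidy()`: the per-truth-site tibble; `glance()`: a one-row tibble
#'   with `n_calls`, `n_matched`, `n_truth`, `precision`, `recall`,
#'   `mean_coord_error`.
#' @export
tidy.aav_eval <- function(x, ...) x$sites

#' @rdname tidy.aav_eval
#' @export
glance.aav_eval <- function(x, ...) {
  tibble::tibble(
    n_calls = x$n_calls, n_matched = x$n_matched, n_truth = nrow(x$sites),
    precision = x$precision, recall = x$recall,
    mean_coord_error = mean(x$sites$coord_error, na.rm = TRUE)
  )
}

#' Tidy pipeline results
#'
#' @param x An `aav_long_result` or `aav_short_result`.
#' @param ... Unused.
#' @return `tidy()`: the events (long) or summary (short) tibble;
#'   `glance()`: the per-stage count table as one row.
#' @export
tidy.aav_long_result <- function(x, ...) tibble::as_tibble(x$events)

#' @rdname tidy.aav_long_result
#' @export
tidy.aav_short_result <- function(x, ...) tibble::as_tibble(x$summary)

#' @rdname tidy.aav_long_result
#' @export
glance.aav_long_result <- function(x, ...) {
  tidyr::pivot_wider(x$stages, names_from = "stage", values_from = "n")
}

#' @rdname tidy.aav_long_result
#' @export
glance.aav_short_result <- function(x, ...) {
  tidyr::pivot_wider(x$stages, names_from = "stage", values_from = "n")
}

#' Write pipeline outputs as TSV/BED with a provenance header
#'
#' @param x An `aav_long_result` or `aav_short_result`.
#' @param prefix Output path prefix; files `<prefix>_events.tsv` /
#'   `<prefix>_summary.tsv`, `<prefix>_annotation.tsv`,
#'   `<prefix>_junctions.bed`, `<prefix>_structures.tsv` are written as
#'   applicable.
#' @param config Optional config recorded in the header.
#' @return Invisibly, the paths written.
#' @export
write_result <- function(x, prefix, config = NULL) {
  hdr <- c(
    paste0("# aavjunct ", as.character(utils::packageVersion("aavjunct"))),
    if (!is.null(config)) paste0("# config_hash=", rlang::hash(unclass(config)))
  )
  paths <- character()
  flat <- function(v) vapply(v, paste, "", collapse = ";")
  if (inherits(x, "aav_long_result")) {
    ev <- dplyr::mutate(tibble::as_tibble(x$events),
                        read_names = flat(.data$read_names),
                        member_positions = flat(.data$member_positions))
    p <- paste0(prefix, "_events.tsv")
    readr::write_lines(hdr, p); readr::write_tsv(ev, p, append = TRUE, col_names = TRUE)
    paths <- c(paths, p)
    if (nrow(x$events)) {
      b <- paste0(prefix, "_junctions.bed")
      write_bed(tibble::tibble(chrom = x$events$chrom,
                               start0 = x$events$pos1 - 1, end0 = x$events$pos1,
                               name = paste0(x$events$side, ":", x$events$support)), b)
      paths <- c(paths, b)
    }
    if (nrow(x$structures)) {
      st <- dplyr::mutate(
        x$structures,
        segments = vapply(.data$segments, function(s)
          paste(sprintf("%d-%d:%s", s$start0, s$end0, s$orient), collapse = ";"), ""),
        alterations = vapply(.data$alterations, function(a)
          paste(sprintf("%s(%s)", a$type, a$size), collapse = ";"), ""),
        junction_gaps = flat(.data$junction_gaps))
      p2 <- paste0(prefix, "_structures.tsv")
      readr::write_tsv(st, p2)
      paths <- c(paths, p2)
    }
  } else if (inherits(x, "aav_short_result")) {
    p <- paste0(prefix, "_summary.tsv")
    readr::write_lines(hdr, p)
    readr::write_tsv(tibble::as_tibble(x$summary), p, append = TRUE, col_names = TRUE)
    a <- paste0(prefix, "_annotation.tsv")
    readr::write_lines(hdr, a)
    readr::write_tsv(x$annotation, a, append = TRUE, col_names = TRUE)
    paths <- c(paths, p, a)
    if (nrow(x$summary)) {
      b <- paste0(prefix, "_junctions.bed")
      write_bed(tibble::tibble(chrom = x$summary$chrom,
                               start0 = x$summary$pos1 - 1, end0 = x$summary$pos1,
                               name = paste0(x$summary$side, ":", x$summary$support)), b)
      paths <- c(paths, b)
    }
  } else {
    stop("unsupported result type")
  }
  invisible(paths)
}
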