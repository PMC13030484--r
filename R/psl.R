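#' Import alignment blocks from BLAT PSL
#'
#' Parses standard 21-column PSL (with or without the psLayout header) into
#' alignment blocks.  Per the PSL convention, query coordinates are already
#' 0-based half-open on the forward-oriented query regardless of strand, and
#' matched bases are `matches + repMatches`.
#'
#' @param x Path to a PSL file, or a character vector of PSL lines.
#' @param ref Optional `aav_hybrid_ref` used to set `is_vector`.
#' @return Blocks tibble; malformed lines are skipped with a warning naming
#'   the line numbers.
#' @export
parse_psl_blocks <- function(x, ref = NULL) {
  lines <- if (length(x) == 1 && file.exists(x)) readr::read_lines(x) else x
  if (!length(lines)) return(empty_blocks())
  is_header <- grepl("^psLayout", lines) | grepl("^-+\\s*$", lines) |
    grepl("^(match|\\s*match)\\b", lines) | grepl("^\\s*$", lines) |
    !grepl("^[0-9]+\t", lines)
  body <- which(!is_header)
  if (!length(body)) return(empty_blocks())

  fields <- strsplit(lines[body], "\t", fixed = TRUE)
  ok <- lengths(fields) >= 21
  if (any(!ok)) {
    warning("skipping malformed PSL line(s): ",
            paste(body[!ok], collapse = ", "))
  }
  keep <- body[ok]
  f <- fields[ok]
  if (!length(f)) return(empty_blocks())

  num <- function(i) as.numeric(vapply(f, `[[`, "", i))
  chr <- function(i) vapply(f, `[[`, "", i)
  matches <- num(1) + num(3)
  q_start <- num(12); q_end <- num(13)
  out <- tibble::tibble(
    read_id = chr(10),
    read_len = as.integer(num(11)),
    read_start = as.integer(q_start),
    read_end = as.integer(q_end),
    strand = substr(chr(9), 1, 1),
    ref_name = chr(14),
    ref_start = num(16),
    ref_end = num(17),
    matches = as.integer(matches),
    aligned_span = as.integer(q_end - q_start),
    score = as.integer(matches - num(2) - num(6) - num(8)),
    source = "psl"
  )
  bad <- out$aligned_span <= 0 | out$matches <= 0 | out$matches > out$aligned_span
  if (any(bad)) {
    warning("skipping inconsistent PSL line(s): ",
            paste(keep[bad], collapse = ", "))
    out <- out[!bad, , drop = FALSE]
  }
  out$match_score <- out$matches / out$aligned_span
  out$is_vector <- if (!is.null(ref)) out$ref_name %in% ref$vector_names else FALSE
  dplyr::arrange(dplyr::select(out, dplyr::all_of(names(empty_blocks()))),
                 .data$read_id, .data$read_start)
}
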