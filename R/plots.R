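#' Plot integration events
#'
#' Lollipop-style support plot of clustered integration events along each
#' chromosome, the baseline site highlighted.
#'
#' @param object An `aav_events` tibble (e.g. `long_result$events`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.aav_events <- function(object, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pos1, y = .data$support)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$pos1, yend = 0),
                          linewidth = 0.4, colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$is_baseline,
                                     shape = .data$side), size = 3) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "steelblue", `TRUE` = "firebrick"),
                                 name = "baseline") +
    ggplot2::labs(x = "host coordinate (bp)", y = "supporting reads",
                  title = "Integration events") +
    ggplot2::theme_minimal()
}

#' Plot per-coordinate junction support
#'
#' @param object An `aav_summary` tibble (e.g. `short_result$summary`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.aav_summary <- function(object, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pos1, y = .data$support,
                                  fill = .data$side)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "host coordinate (bp)", y = "supporting reads",
                  title = "Short-read junction support") +
    ggplot2::theme_minimal()
}

#' Plot cross-method concordance
#'
#' One point per called site, positioned at its coordinate and coloured by
#' whether both methods, only the long-read caller, or only the short-read
#' caller found it.
#'
#' @param object An `aav_concordance` tibble from [compare_callsets()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.aav_concordance <- function(object, ...) {
  d <- tibble::as_tibble(object) %>%
    dplyr::mutate(pos1 = dplyr::coalesce(.data$pos1_long, .data$pos1_short))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pos1, y = .data$chrom,
                                  colour = .data$status)) +
    ggplot2::geom_point(size = 3, alpha = 0.8) +
    ggplot2::labs(x = "host coordinate (bp)", y = NULL,
                  title = "Cross-method concordance") +
    ggplot2::theme_minimal()
}
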