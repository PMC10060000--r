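#' @method autoplot line_scan_set
#' @export
autoplot.line_scan_set <- function(object, lines = NULL, ...) {
  d <- object$data
  if (!is.null(lines)) d <- d[d$line_index %in% lines, ]
  ylab <- if (object$normalized) "intensity (counts/s)" else
    "intensity (counts)"
  ggplot2::ggplot(d, ggplot2::aes(.data$time_s, .data$intensity,
                                  color = .data$transition_id)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~line_index, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "time (s)", y = ylab, color = "transition")
}

#' Plot per-ROI summary statistics
#'
#' Bar chart of ROI means with SD error bars, the standard presentation of
#' per-region analyte abundances.
#'
#' @param summary A tibble from [roi_summary()] (optionally row-bound over
#'   several images with an extra identifying column passed as `facet`).
#' @param facet Optional column name to facet by.
#' @return A ggplot object.
#' @export
plot_roi_summary <- function(summary, facet = NULL) {
  p <- ggplot2::ggplot(summary,
                       ggplot2::aes(.data$roi, .data$mean,
                                    fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean,
                                        ymax = .data$mean + .data$sd),
                           width = 0.3) +
    ggplot2::labs(x = NULL, y = "mean intensity (counts/s)")
  if (!is.null(facet)) {
    p <- p + ggplot2::facet_wrap(stats::as.formula(paste("~", facet)),
                                 scales = "free_y")
  }
  p
}
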