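# ggplot2 visualisations for traces, calibration curves, schedules and
# sweep summaries.

#' Plot extracted ion chromatograms
#'
#' @param traces Row-bound traces from [extract_xic()] (one or more
#'   fragments, one or both labels).
#' @return A ggplot: intensity vs. RT, coloured by fragment, faceted by
#'   label when both are present.
#' @export
plot_traces <- function(traces) {
  p <- ggplot2::ggplot(traces,
                       ggplot2::aes(x = .data$rt, y = .data$intensity,
                                    colour = .data$fragment)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "retention time (min)", y = "intensity (counts)",
                  colour = "transition") +
    ggplot2::theme_minimal()
  if (length(unique(traces$label)) > 1) {
    p <- p + ggplot2::facet_wrap(~label, scales = "free_y")
  }
  p
}

#' @export
#' @method autoplot prm_calibration
autoplot.prm_calibration <- function(object, ...) {
  lv <- object$levels
  ggplot2::ggplot(lv, ggplot2::aes(x = .data$nominal, y = .data$response)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         linetype = 2, colour = "grey40") +
    { if (!is.na(object$loq))
        ggplot2::geom_vline(xintercept = object$loq, colour = "firebrick",
                            linetype = 3) } +
    ggplot2::scale_x_continuous(trans = "log2") +
    ggplot2::scale_y_continuous(trans = "log2") +
    ggplot2::labs(x = "nominal amount (amol)", y = "response (L/H ratio)",
                  title = object$peptide,
                  subtitle = sprintf("R² = %.4f, LOQ = %s amol",
                                     object$r2,
                                     if (is.na(object$loq)) "n.d."
                                     else signif(object$loq, 3))) +
    ggplot2::theme_minimal()
}

#' @export
#' @method autoplot prm_schedule
autoplot.prm_schedule <- function(object, ...) {
  tg <- object$targets
  tg$y <- seq_len(nrow(tg))
  prof <- concurrency_profile(object)$profile
  ggplot2::ggplot(tg) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$window_start,
                                       xend = .data$window_end,
                                       y = .data$y, yend = .data$y,
                                       colour = .data$protein),
                          linewidth = 2) +
    ggplot2::labs(x = "retention time (min)", y = "scheduled target",
                  title = sprintf("max concurrency %d pairs",
                                  object$max_concurrency_observed)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a parameter-sweep summary
#'
#' @param sweep Output of [parameter_sweep()].
#' @param metric Column to display (default `mean_dotp`).
#' @return A ggplot of the metric over the grid.
#' @export
plot_sweep <- function(sweep, metric = "mean_dotp") {
  var <- names(sweep)[1]
  ggplot2::ggplot(sweep, ggplot2::aes(x = factor(.data[[var]]),
                                      y = .data[[metric]])) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = var, y = metric) +
    ggplot2::theme_minimal()
}
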