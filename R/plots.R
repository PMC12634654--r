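#' Forest plot of signal strength
#'
#' Reporting odds ratios with 95% confidence intervals per event, flagged
#' signals highlighted, on a log x-scale with the null at 1.
#'
#' @param object A `pv_signal_table` from [signal_stats()].
#' @param k Show only the top `k` events by ROR.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pv_signal_table <- function(object, k = 30, ...) {
  rows <- rank_signals(object, by = "ror", k = k)
  rows <- rows[!is.na(rows$ror), ]
  rows$event <- factor(rows$event, levels = rev(rows$event))
  ggplot2::ggplot(rows, ggplot2::aes(x = ror, y = event, colour = signal)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = ror_low, xmax = ror_high), height = 0.2
    ) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Reporting odds ratio (95% CI)", y = NULL,
                  colour = "Signal") +
    ggplot2::theme_minimal()
}

#' Monthly time-to-onset histogram plot
#'
#' Bar chart of case counts per 30-day onset month with the percentage of
#' the sample labelled on each bar.
#'
#' @param sample A `pv_tto` tibble or numeric vector of onset days.
#' @return A ggplot object.
#' @export
plot_monthly_histogram <- function(sample) {
  bins <- monthly_histogram(sample)
  ggplot2::ggplot(bins, ggplot2::aes(x = month, y = count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = paste0(percent, "%")),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = "Month after therapy start (30-day bins)",
                  y = "Reported cases") +
    ggplot2::theme_minimal()
}

#' Cumulative incidence plot
#'
#' Empirical CDF of onset in percent, with the median and interquartile
#' range marked.
#'
#' @param sample A `pv_tto` tibble or numeric vector of onset days.
#' @return A ggplot object.
#' @export
plot_cumulative_incidence <- function(sample) {
  curve <- cumulative_incidence(sample)
  med <- attr(curve, "median")
  ggplot2::ggplot(curve, ggplot2::aes(x = day, y = cum_percent)) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(xintercept = med, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = c(attr(curve, "q1"), attr(curve, "q3")),
                        linetype = "dotted") +
    ggplot2::labs(x = "Days from therapy start",
                  y = "Cumulative percent of reports") +
    ggplot2::theme_minimal()
}
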