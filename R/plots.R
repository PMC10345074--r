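# Figure helpers: circadian mean +/- SD curves with the shaded night
# window and per-hour significance stars, and importance bar charts.

#' Plot group circadian profiles
#'
#' Hour-of-day mean curves per outcome group with an SD ribbon, a shaded
#' night window (22:00-05:00) and stars at hours whose Bonferroni-corrected
#' Mann-Whitney test is significant.
#'
#' @param summary Output of [cohort_profile_summary()].
#' @param hourly_tests Optional output of [hourly_group_test()].
#' @param ylab Axis label (e.g. `"HR [bpm]"`).
#' @param night_hours Clock hours shaded as night.
#' @return A ggplot object.
#' @export
plot_circadian_profile <- function(summary, hourly_tests = NULL,
                                   ylab = "HR [bpm]",
                                   night_hours = c(22, 23, 0, 1, 2, 3, 4)) {
  ymax <- max(summary$mean + summary$sd, na.rm = TRUE)
  shade <- data.frame(xmin = c(-0.5, 21.5), xmax = c(4.5, 23.5))
  p <- ggplot2::ggplot(summary, ggplot2::aes(x = .data$hour, y = .data$mean,
                                             colour = .data$group,
                                             fill = .data$group)) +
    ggplot2::geom_rect(data = shade,
                       ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax),
                       ymin = -Inf, ymax = Inf, fill = "grey85",
                       colour = NA, inherit.aes = FALSE) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Hour of day", y = ylab, colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(hourly_tests)) {
    sig <- hourly_tests[hourly_tests$significant, , drop = FALSE]
    if (nrow(sig))
      p <- p + ggplot2::annotate("text", x = sig$hour, y = ymax * 1.02,
                                 label = "*", size = 5)
  }
  p
}

#' Bar chart of mean unit-norm feature importances
#'
#' @param cv A `circdip_cv` result.
#' @return A ggplot object.
#' @export
plot_feature_importance <- function(cv) {
  d <- data.frame(feature = names(cv$mean_importance),
                  importance = as.numeric(cv$mean_importance))
  d$feature <- stats::reorder(d$feature, d$importance)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$feature, y = .data$importance)) +
    ggplot2::geom_col(fill = "steelblue") + ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Normalized importance") +
    ggplot2::theme_minimal()
}
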