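# ggplot2 display helpers for the result types.

#' @describeIn cumulative_fraction Plot a cumulative activation curve.
#' @param object A `"cumulative_curve"`.
#' @param ... Unused.
#' @export
autoplot.cumulative_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_h,
                                       y = .data$fraction)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time (h)", y = "cumulative fraction of cells",
                  title = unique(object$event_name)) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot an aligned-median band
#'
#' @param med Tibble from [median_with_ci()].
#' @param ylab Y-axis label.
#' @return A ggplot object.
#' @export
plot_aligned_median <- function(med, ylab = "activity") {
  ggplot2::ggplot(med, ggplot2::aes(x = .data$relative_time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$median), colour = "red") +
    ggplot2::labs(x = "time relative to anchor (h)", y = ylab) +
    ggplot2::theme_minimal()
}

#' Plot stress exit fractions by CDK2 bin
#'
#' @param bins Tibble from [stress_exit_by_cdk2_bin()].
#' @return A ggplot object.
#' @export
plot_stress_bins <- function(bins) {
  ggplot2::ggplot(bins, ggplot2::aes(x = factor(round(.data$bin_center, 2)),
                                     y = .data$fraction_low)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "CDK2 activity at stress", y = "fraction exiting") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Phase-plane plot of CDK2 versus corrected CDK4/6 (time colour-coded)
#'
#' @param traj Tibble from [phase_trajectory()].
#' @return A ggplot object.
#' @export
plot_phase_trajectory <- function(traj) {
  ggplot2::ggplot(traj, ggplot2::aes(x = .data$cdk46_med,
                                     y = .data$cdk2_med,
                                     colour = .data$time_h)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_colour_viridis_c(name = "time (h)") +
    ggplot2::labs(x = "corrected CDK4/6 activity", y = "CDK2 activity") +
    ggplot2::theme_minimal()
}
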