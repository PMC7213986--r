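#' Corrected CDK4/6 activity
#'
#' Removes the additive CDK2 cross-contribution from the raw CDK4/6 reporter:
#'
#' `corrected = cdk46_raw - f * cdk2`
#'
#' with `f = 0.35` by default. Masked samples (`NA`) in either input
#' propagate to the output. Negative corrected values are kept: clipping is a
#' display concern, and preserving the noise structure matters for the
#' statistics downstream.
#'
#' @param cdk46_raw Raw CDK4/6 reporter series (cytoplasmic:nuclear ratio).
#' @param cdk2 Simultaneous CDK2 reporter series, same length.
#' @param f CDK2 contamination fraction in `[0, 1]`.
#' @return Corrected CDK4/6 activity series.
#' @examples
#' corrected_cdk46(1.0, 0.76)  # 0.734
#' @export
corrected_cdk46 <- function(cdk46_raw, cdk2,
                            f = default_thresholds()$f_correction) {
  if (length(cdk46_raw) != length(cdk2)) {
    abort("cdk46_raw and cdk2 must have the same length",
          class = "cdktrace_shape_error")
  }
  if (length(f) != 1 || is.na(f) || f < 0 || f > 1) {
    abort("f must be a scalar in [0, 1]", class = "cdktrace_parameter_error")
  }
  cdk46_raw - f * cdk2
}

#' Add a corrected CDK4/6 column to a cohort's track table
#'
#' @param cohort A `"cdk_cohort"`.
#' @param f CDK2 contamination fraction.
#' @return The cohort with a `cdk46_corr` column in `$traces`.
#' @export
add_corrected <- function(cohort, f = default_thresholds()$f_correction) {
  cohort$traces$cdk46_corr <- corrected_cdk46(cohort$traces$cdk46_raw,
                                              cohort$traces$cdk2, f)
  cohort
}

#' Estimate the CDK2 contamination fraction from a CDK4/6-inhibition cohort
#'
#' After acute CDK4/6 inhibition the CDK4/6-specific signal is nulled, so
#' whatever raw reporter signal remains in S/G2 cells tracks CDK2 activity.
#' Pooling (cell, frame) points from `t_add + 2` frames (letting the
#' inhibition equilibrate) to `t_add + window`, the estimator fits the
#' ordinary least-squares regression
#'
#' `cdk46_raw ~ intercept + f * cdk2`
#'
#' across the pooled points and reports the slope as `f_hat`. Only cells
#' whose APC/C degron was already rising before `t_add` (S/G2 cells) enter
#' the fit; G1 cells are excluded because CDK4/6 inhibition reverses their
#' CDK2 trajectory. `flatness` is the absolute slope (activity/hour) of the
#' corrected signal `cdk46_raw - f_hat * cdk2` against time over the fitting
#' window: near zero when the correction removes the CDK2 contribution.
#'
#' @param cohort A `"cdk_cohort"` carrying a `cdk46_inhibitor` perturbation.
#' @param t_add Hours at which the inhibitor was added (defaults to the
#'   cohort's perturbation spec).
#' @param window Hours after `t_add` to include (default 4).
#' @param thresholds Thresholds (for the degron rise detector).
#' @param smooth_window Running-median window used when locating the degron
#'   rise (default 3).
#' @return A `"correction_fit"` with fields `f_hat`, `stderr`, `n_points`,
#'   `n_cells`, `flatness`; supports [tidy()] and [glance()].
#' @export
estimate_correction_factor <- function(cohort, t_add = NULL, window = 4,
                                       thresholds = default_thresholds(),
                                       smooth_window = 3) {
  pert <- cohort$perturbation
  if (is.null(t_add)) {
    if (is.null(pert)) {
      abort("cohort carries no perturbation and no t_add was given",
            class = "cdktrace_protocol_error")
    }
    t_add <- pert$t_add
  }
  if (!is.null(pert) && pert$kind != "cdk46_inhibitor") {
    abort("cohort perturbation is not a CDK4/6 inhibitor",
          class = "cdktrace_protocol_error")
  }
  if (is.null(pert) && is.null(t_add)) {
    abort("no CDK4/6 inhibitor perturbation in cohort metadata",
          class = "cdktrace_protocol_error")
  }
  tr <- cohort$traces
  dt <- stats::median(diff(sort(unique(tr$time_h))))

  # S/G2 gate: degron rising before the inhibitor was added
  sm <- smooth_cohort(cohort, window = smooth_window)
  apc_rise <- sm$traces |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(t_apc = detect_apc_off(.data$apc_degron, .data$time_h,
                                            k_sigma = thresholds$k_sigma),
                     .groups = "drop")
  sg2_ids <- apc_rise$cell_id[!is.na(apc_rise$t_apc) &
                                apc_rise$t_apc < t_add]

  pts <- tr |>
    dplyr::filter(.data$cell_id %in% sg2_ids,
                  .data$time_h >= t_add + 2 * dt,
                  .data$time_h <= t_add + window,
                  !is.na(.data$cdk46_raw), !is.na(.data$cdk2))
  if (nrow(pts) < 10) {
    abort(sprintf(
      "insufficient data: %d eligible (cell, frame) points, need >= 10",
      nrow(pts)), class = "cdktrace_insufficient_data_error")
  }
  fit <- lm(cdk46_raw ~ cdk2, data = pts)
  f_hat <- unname(coef(fit)[["cdk2"]])
  se <- summary(fit)$coefficients["cdk2", "Std. Error"]
  pts$corr <- pts$cdk46_raw - f_hat * pts$cdk2
  flat_fit <- lm(corr ~ time_h, data = pts)
  flatness <- abs(unname(coef(flat_fit)[["time_h"]]))

  structure(
    list(f_hat = f_hat, stderr = se, n_points = nrow(pts),
         n_cells = length(unique(pts$cell_id)), flatness = flatness,
         t_add = t_add, window = window,
         intercept = unname(coef(fit)[["(Intercept)"]])),
    class = "correction_fit")
}

#' @export
print.correction_fit <- function(x, ...) {
  cat("<correction_fit>\n")
  cat(sprintf("  f_hat    = %.4f (se %.4f)\n", x$f_hat, x$stderr))
  cat(sprintf("  points   = %d from %d S/G2 cells, window [%g, %g] h\n",
              x$n_points, x$n_cells, x$t_add, x$t_add + x$window))
  cat(sprintf("  flatness = %.2g activity/h after correction\n", x$flatness))
  invisible(x)
}

#' @rdname estimate_correction_factor
#' @param x A `"correction_fit"`.
#' @param ... Unused.
#' @export
tidy.correction_fit <- function(x, ...) {
  tibble::tibble(term = "cdk2_contamination_fraction",
                 estimate = x$f_hat, std.error = x$stderr)
}

#' @rdname estimate_correction_factor
#' @export
glance.correction_fit <- function(x, ...) {
  tibble::tibble(f_hat = x$f_hat, stderr = x$stderr, n_points = x$n_points,
                 n_cells = x$n_cells, flatness = x$flatness)
}
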