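#' Detect an activation onset by sustained threshold crossing
#'
#' Returns the first grid time `t` at which the series exceeds `theta` at `t`
#' and at every unmasked sample in `[t, t + persistence]` (the window is
#' clipped at the end of the trace), or `NA` if no such time exists. The
#' onset is reported as the first above-threshold frame, not an interpolated
#' crossing, so results are grid-aligned and reproducible. The series is
#' expected to be smoothed upstream.
#'
#' @param series Activity series (possibly with masked `NA` samples).
#' @param times Matching time grid, hours.
#' @param theta Activity threshold.
#' @param persistence Hours the crossing must be sustained (>= the frame
#'   interval).
#' @return Onset time in hours, or `NA_real_`.
#' @export
detect_onset <- function(series, times, theta, persistence) {
  if (length(series) != length(times)) {
    abort("series and times must have the same length",
          class = "cdktrace_shape_error")
  }
  if (length(times) == 0) return(NA_real_)
  span <- times[length(times)] - times[1]
  if (persistence > span) {
    abort("persistence exceeds the trace span",
          class = "cdktrace_parameter_error")
  }
  above <- series > theta          # NA where masked
  for (i in seq_along(times)) {
    if (is.na(above[i]) || !above[i]) next
    w <- which(times >= times[i] & times <= times[i] + persistence)
    ok <- above[w]
    if (all(ok[!is.na(ok)])) return(times[i])
  }
  NA_real_
}

#' Detect the onset of APC/C-degron accumulation (APC/C-off point)
#'
#' Estimates baseline mean and sd from the flat pre-rise segment (expanding
#' from the start of the series) and returns the first time the degron
#' exceeds `baseline + k_sigma * sd` with the rise sustained over the
#' following hour: every unmasked sample in that hour stays above the
#' threshold and the (lightly smoothed) signal does not decrease net over
#' the window. Returns `NA` when the degron never rises.
#'
#' @param degron Nonnegative degron intensity series.
#' @param times Matching time grid, hours.
#' @param k_sigma Baseline-noise multiplier (default 3).
#' @param sustain Hours the rise must be sustained (default 1).
#' @return Rise-onset time in hours, or `NA_real_`.
#' @export
detect_apc_off <- function(degron, times, k_sigma = 3, sustain = 1) {
  ok <- !is.na(degron)
  if (sum(ok) < 10) {
    abort("need >= 10 unmasked degron samples",
          class = "cdktrace_insufficient_data_error")
  }
  sm <- smooth_series(degron, 3)
  n <- length(times)
  base_n <- 10L
  repeat {
    idx <- which(ok)[seq_len(min(base_n, sum(ok)))]
    mu <- mean(degron[idx])
    sdv <- sd(degron[idx])
    if (!is.finite(sdv)) sdv <- 0
    thr <- mu + k_sigma * sdv
    cand <- NA_integer_
    for (i in seq_len(n)) {
      if (is.na(degron[i]) || degron[i] <= thr) next
      w <- which(times > times[i] & times <= times[i] + sustain)
      vals <- degron[w]
      vals <- vals[!is.na(vals)]
      # a blip on the final frames with no follow-up is not a rise
      sustained <- length(vals) >= 2 && all(vals > thr)
      net_rise <- length(w) > 0 &&
        (is.na(sm[max(w)]) || is.na(sm[i]) || sm[max(w)] >= sm[i])
      if (sustained && net_rise) { cand <- i; break }
    }
    if (is.na(cand)) return(NA_real_)
    # expand the baseline to everything before the candidate and re-test once
    pre <- which(ok & seq_len(n) < cand)
    if (length(pre) >= 10 && length(pre) > base_n) {
      mu2 <- mean(degron[pre]); sd2 <- sd(degron[pre])
      thr2 <- mu2 + k_sigma * max(sd2, 0)
      if (degron[cand] > thr2 || abs(thr2 - thr) < 1e-12) {
        return(times[cand])
      }
      base_n <- length(pre)
    } else {
      return(times[cand])
    }
  }
}

#' Detect per-cell event landmarks for a whole cohort
#'
#' Smooths each channel with a running median, computes corrected CDK4/6
#' activity, and detects per cell: the CDK4/6-on point (corrected CDK4/6
#' above `theta_cdk46`, sustained `persistence_window` hours), the CDK2-on
#' point (CDK2 above `theta_cdk2`, sustained `persistence_cdk2` hours), and
#' the APC/C-off point (degron rise). For cycling cohorts detection starts
#' at each cell's first anaphase, which is also recorded as the alignment
#' anchor `t_anaphase_ref`.
#'
#' @param cohort A `"cdk_cohort"`.
#' @param thresholds A [default_thresholds()] list.
#' @param smooth_window Running-median window in samples (default 3).
#' @return Tibble with one row per cell: `cell_id`, `t_cdk46_on`,
#'   `t_cdk2_on`, `t_apc_off`, `t_anaphase_ref`.
#' @export
detect_events <- function(cohort, thresholds = default_thresholds(),
                          smooth_window = 3) {
  sm <- smooth_cohort(cohort, window = smooth_window)
  sm$traces$cdk46_corr <- corrected_cdk46(sm$traces$cdk46_raw,
                                          sm$traces$cdk2,
                                          thresholds$f_correction)
  sm$traces |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_modify(function(df, key) {
      ana <- df$time_h[df$is_anaphase %in% TRUE]
      anchor <- if (length(ana) > 0) min(ana) else NA_real_
      keep <- if (is.na(anchor)) rep(TRUE, nrow(df)) else
        df$time_h >= anchor
      tt <- df$time_h[keep]
      tibble::tibble(
        t_cdk46_on = detect_onset(df$cdk46_corr[keep], tt,
                                  thresholds$theta_cdk46,
                                  thresholds$persistence_window),
        t_cdk2_on = detect_onset(df$cdk2[keep], tt,
                                 thresholds$theta_cdk2,
                                 thresholds$persistence_cdk2),
        t_apc_off = detect_apc_off(df$apc_degron[keep], tt,
                                   k_sigma = thresholds$k_sigma),
        t_anaphase_ref = anchor
      )
    }) |>
    dplyr::ungroup()
}

#' Coarse cell-cycle phase of a cell at a given time
#'
#' `post_G1S` iff `t >= t_apc_off`; `G1_active` iff
#' `t_cdk46_on <= t < t_apc_off` (or no APC/C-off detected); otherwise
#' `pre_activation`.
#'
#' @param record One-row event record (as produced by [detect_events()]).
#' @param t Time in hours.
#' @return `"pre_activation"`, `"G1_active"` or `"post_G1S"`.
#' @export
phase_at_time <- function(record, t) {
  t_apc <- record$t_apc_off
  t46 <- record$t_cdk46_on
  if (!is.na(t_apc) && t >= t_apc) return("post_G1S")
  if (!is.na(t46) && t >= t46) return("G1_active")
  "pre_activation"
}

#' Write an event table to CSV
#'
#' @param records Event tibble from [detect_events()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(records, path) {
  readr::write_csv(records, path, progress = FALSE)
  invisible(path)
}
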