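#' Running-median smoothing of an activity series
#'
#' Centered running median with an odd window. Near the edges the window
#' shrinks symmetrically (to 1 at the first and last sample), so the series
#' length never changes and `window = 1` returns the input unchanged. Masked
#' samples (`NA`) are excluded from each window and remain masked in the
#' output: smoothing never invents data at a masked position.
#'
#' @param x Numeric series, possibly with `NA` (masked) entries.
#' @param window Odd positive integer, at most `length(x)`.
#' @return Smoothed numeric series of the same length.
#' @examples
#' smooth_series(c(0, 10, 0, 0, 0), 3)
#' @export
smooth_series <- function(x, window = 3) {
  n <- length(x)
  if (length(window) != 1 || is.na(window) || window < 1 ||
      window %% 2 == 0 || window > n) {
    abort("window must be an odd integer in [1, length(x)]",
          class = "cdktrace_parameter_error")
  }
  if (window == 1) return(x)
  half <- (window - 1) / 2
  out <- x
  for (i in seq_len(n)) {
    if (is.na(x[i])) next  # masked stays masked
    h <- min(half, i - 1, n - i)
    w <- x[(i - h):(i + h)]
    out[i] <- stats::median(w, na.rm = TRUE)
  }
  out
}

#' Smooth one cell's trace
#'
#' Applies [smooth_series()] to each activity channel (`cdk46_raw`, `cdk2`,
#' `apc_degron`) of a single-cell slice of the track table.
#'
#' @param trace Long tibble for one cell (rows ordered or orderable by
#'   `time_h`).
#' @param window Odd running-median window in samples (default 3).
#' @return Tibble with the same rows, smoothed activity columns.
#' @export
smooth_trace <- function(trace, window = 3) {
  trace <- dplyr::arrange(tibble::as_tibble(trace), .data$time_h)
  for (col in c("cdk46_raw", "cdk2", "apc_degron")) {
    if (col %in% names(trace)) trace[[col]] <- smooth_series(trace[[col]], window)
  }
  trace
}

#' Smooth every trace in a cohort
#'
#' @param cohort A `"cdk_cohort"`.
#' @param window Odd running-median window in samples (default 3).
#' @return The cohort with smoothed activity channels.
#' @export
smooth_cohort <- function(cohort, window = 3) {
  cohort$traces <- cohort$traces |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_modify(~ smooth_trace(.x, window = window)) |>
    dplyr::ungroup() |>
    dplyr::relocate("cell_id")
  cohort
}
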