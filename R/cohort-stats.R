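# Population-level statistics over cohorts: event alignment, cumulative
# activation curves, bootstrap median bands, stress dose dependence,
# phase-plane trajectories, and live-fixed Rb phosphorylation matching.

#' Align traces to a per-cell anchor event
#'
#' Shifts each cell's time axis so its anchor maps to relative time 0 and
#' places the chosen channel on a common relative grid spanning the union of
#' shifted spans. Cells lacking the anchor are dropped (their count is
#' reported in the `n_dropped` attribute).
#'
#' @param cohort A `"cdk_cohort"`.
#' @param records Event tibble from [detect_events()] (needed for anaphase
#'   and CDK2-on anchors).
#' @param anchor_kind `"mitogen_release"` (anchor 0), `"anaphase"` or
#'   `"cdk2_on"`.
#' @param channel Which signal to align: `"cdk46_corr"` (default, computed
#'   with the thresholds' correction factor), `"cdk46_raw"`, `"cdk2"` or
#'   `"apc_degron"`.
#' @param thresholds Thresholds list (for the correction factor).
#' @return An `"aligned_matrix"`: list with `relative_times` (hours),
#'   `values` (cells x timepoints matrix, `NA` outside each cell's span),
#'   `cell_ids`, `anchor_kind`.
#' @export
align_to_event <- function(cohort, records = NULL,
                           anchor_kind = c("mitogen_release", "anaphase",
                                           "cdk2_on"),
                           channel = c("cdk46_corr", "cdk46_raw", "cdk2",
                                       "apc_degron"),
                           thresholds = default_thresholds()) {
  anchor_kind <- match.arg(anchor_kind)
  channel <- match.arg(channel)
  tr <- cohort$traces
  if (channel == "cdk46_corr" && !"cdk46_corr" %in% names(tr)) {
    tr$cdk46_corr <- corrected_cdk46(tr$cdk46_raw, tr$cdk2,
                                     thresholds$f_correction)
  }
  ids <- unique(tr$cell_id)
  anchors <- switch(
    anchor_kind,
    mitogen_release = setNames(rep(0, length(ids)), ids),
    anaphase = {
      a <- tr |>
        dplyr::filter(.data$is_anaphase %in% TRUE) |>
        dplyr::group_by(.data$cell_id) |>
        dplyr::summarise(a = min(.data$time_h), .groups = "drop")
      setNames(a$a, a$cell_id)[ids]
    },
    cdk2_on = {
      if (is.null(records)) {
        abort("records are required for the cdk2_on anchor",
              class = "cdktrace_parameter_error")
      }
      setNames(records$t_cdk2_on, records$cell_id)[ids]
    })
  keep <- ids[!is.na(anchors[ids])]
  n_dropped <- length(ids) - length(keep)
  if (length(keep) == 0) {
    abort("no cell has the requested anchor",
          class = "cdktrace_insufficient_data_error")
  }
  dt <- stats::median(diff(sort(unique(tr$time_h))))
  shifted <- tr |>
    dplyr::filter(.data$cell_id %in% keep) |>
    dplyr::mutate(rel = .data$time_h - unname(anchors[.data$cell_id]))
  rel_grid <- seq(round(min(shifted$rel) / dt),
                  round(max(shifted$rel) / dt)) * dt
  mat <- matrix(NA_real_, nrow = length(keep), ncol = length(rel_grid),
                dimnames = list(keep, NULL))
  col_of <- function(rel) round(rel / dt) - round(min(shifted$rel) / dt) + 1
  mat[cbind(match(shifted$cell_id, keep), col_of(shifted$rel))] <-
    shifted[[channel]]
  structure(list(relative_times = rel_grid, values = mat,
                 cell_ids = keep, anchor_kind = anchor_kind,
                 channel = channel, n_dropped = n_dropped),
            class = "aligned_matrix")
}

#' @export
print.aligned_matrix <- function(x, ...) {
  cat(sprintf("<aligned_matrix> %d cells x %d timepoints, anchor = %s, channel = %s\n",
              nrow(x$values), ncol(x$values), x$anchor_kind, x$channel))
  if (x$n_dropped > 0) cat(sprintf("  %d cell(s) dropped (no anchor)\n",
                                   x$n_dropped))
  invisible(x)
}

#' Cumulative fraction of cells attaining an event
#'
#' `fraction(t)` is the number of cells whose event time is at most `t`
#' divided by the total number of tracked cells; cells that never attain the
#' event stay in the denominator (right-censoring), matching "fraction of
#' cells activating as a function of time".
#'
#' @param records Event tibble from [detect_events()].
#' @param event_name One of `"t_cdk46_on"`, `"t_cdk2_on"`, `"t_apc_off"`,
#'   or any time column of `records`.
#' @param times Evaluation grid, hours.
#' @param relative_to Optional column (e.g. `"t_anaphase_ref"`) subtracted
#'   from the event times before counting.
#' @return A `"cumulative_curve"` tibble: `time_h`, `fraction`, `n_total`,
#'   `event_name`.
#' @export
cumulative_fraction <- function(records, event_name, times,
                                relative_to = NULL) {
  if (!event_name %in% names(records)) {
    abort(paste0("unknown event_name: ", event_name),
          class = "cdktrace_parameter_error")
  }
  if (nrow(records) < 1) {
    abort("need at least one record",
          class = "cdktrace_insufficient_data_error")
  }
  ev <- records[[event_name]]
  if (!is.null(relative_to)) ev <- ev - records[[relative_to]]
  n_total <- nrow(records)
  frac <- vapply(times, function(t) sum(!is.na(ev) & ev <= t) / n_total,
                 numeric(1))
  structure(tibble::tibble(time_h = times, fraction = frac,
                           n_total = n_total, event_name = event_name),
            class = c("cumulative_curve", "tbl_df", "tbl", "data.frame"))
}

#' Per-timepoint median with a bootstrap confidence band
#'
#' Median across unmasked rows of an aligned matrix at each relative
#' timepoint, with a 95% interval from `n_boot` bootstrap resamples over
#' cells (frames within a cell are dependent, so resampling is over whole
#' rows). Seeded and reproducible.
#'
#' @param aligned An `"aligned_matrix"`.
#' @param n_boot Bootstrap resamples (default 500).
#' @param seed Integer seed.
#' @param min_cells Minimum unmasked rows required per timepoint for the
#'   median to be reported (default 3).
#' @return Tibble: `relative_time`, `n`, `median`, `lo`, `hi`.
#' @export
median_with_ci <- function(aligned, n_boot = 500, seed = 1,
                           min_cells = 3) {
  m <- aligned$values
  if (nrow(m) < 10) {
    abort("need >= 10 aligned cells for a bootstrap band",
          class = "cdktrace_insufficient_data_error")
  }
  set.seed(seed)
  med <- apply(m, 2, median, na.rm = TRUE)
  n_per <- colSums(!is.na(m))
  boots <- matrix(NA_real_, nrow = n_boot, ncol = ncol(m))
  for (b in seq_len(n_boot)) {
    rows <- sample.int(nrow(m), replace = TRUE)
    boots[b, ] <- apply(m[rows, , drop = FALSE], 2, median, na.rm = TRUE)
  }
  lo <- apply(boots, 2, quantile, probs = 0.025, na.rm = TRUE, names = FALSE)
  hi <- apply(boots, 2, quantile, probs = 0.975, na.rm = TRUE, names = FALSE)
  out <- tibble::tibble(relative_time = aligned$relative_times,
                        n = n_per, median = med, lo = lo, hi = hi)
  out$median[out$n < min_cells] <- NA_real_
  out$lo[out$n < min_cells] <- NA_real_
  out$hi[out$n < min_cells] <- NA_real_
  out
}

#' Stress-induced exit fraction binned by CDK2 activity at stress
#'
#' Bins eligible cells (active CDK4/6 and CDK2, flat degron at the
#' perturbation time) by their smoothed CDK2 activity when the stress was
#' added and reports, per bin, the fraction classified `low` (cell-cycle
#' exit) at the outcome time. Default bins are 0.1 wide from the CDK2-on
#' threshold up to 1.2 with an open top bin. Bins with fewer than 5 cells
#' are flagged low-confidence.
#'
#' @param cohort A stressed `"cdk_cohort"`.
#' @param records Event tibble; computed if `NULL`.
#' @param fates Stress-outcome fate tibble from [classify_cohort()];
#'   computed if `NULL`.
#' @param thresholds Thresholds list.
#' @param bin_edges Increasing CDK2 bin edges; `Inf` appended if absent.
#' @param smooth_window Running-median window (default 3).
#' @return Tibble: `bin_lo`, `bin_hi`, `bin_center`, `n`, `fraction_low`,
#'   `low_confidence`.
#' @export
stress_exit_by_cdk2_bin <- function(cohort, records = NULL, fates = NULL,
                                    thresholds = default_thresholds(),
                                    bin_edges = NULL, smooth_window = 3) {
  if (is.null(cohort$perturbation) ||
      cohort$perturbation$kind != "stress") {
    abort("cohort carries no stress perturbation",
          class = "cdktrace_protocol_error")
  }
  if (is.null(records)) records <- detect_events(cohort, thresholds,
                                                 smooth_window)
  if (is.null(fates)) {
    fates <- classify_cohort(cohort, records, context = "stress_outcome",
                             thresholds = thresholds,
                             smooth_window = smooth_window)
  }
  if (is.null(bin_edges)) {
    bin_edges <- seq(thresholds$theta_cdk2, 1.2, by = 0.1)
  }
  if (is.finite(bin_edges[length(bin_edges)])) bin_edges <- c(bin_edges, Inf)

  cdk2_at <- stress_eligible(cohort, records, thresholds, smooth_window) |>
    dplyr::select("cell_id", cdk2_at_stress = "cdk2_at_perturb")
  df <- fates |>
    dplyr::filter(.data$eligible %in% TRUE) |>
    dplyr::left_join(cdk2_at, by = "cell_id")
  if (nrow(df) == 0) {
    abort("no eligible cells for stress binning",
          class = "cdktrace_insufficient_data_error")
  }
  df$bin <- cut(df$cdk2_at_stress, breaks = bin_edges, right = FALSE,
                include.lowest = TRUE)
  lv <- levels(df$bin)
  lo <- bin_edges[-length(bin_edges)]
  hi <- bin_edges[-1]
  out <- df |>
    dplyr::filter(!is.na(.data$bin)) |>
    dplyr::group_by(.data$bin, .drop = FALSE) |>
    dplyr::summarise(n = dplyr::n(),
                     fraction_low = mean(.data$label == "low"),
                     .groups = "drop") |>
    dplyr::mutate(bin_lo = lo[match(.data$bin, lv)],
                  bin_hi = hi[match(.data$bin, lv)],
                  bin_center = ifelse(is.finite(.data$bin_hi),
                                      (.data$bin_lo + .data$bin_hi) / 2,
                                      .data$bin_lo + 0.05),
                  low_confidence = .data$n < 5) |>
    dplyr::select("bin_lo", "bin_hi", "bin_center", "n", "fraction_low",
                  "low_confidence")
  out
}

#' Group-median phase-plane trajectory (CDK2 versus corrected CDK4/6)
#'
#' Per-timepoint medians of corrected CDK4/6 and CDK2 over a group of cells,
#' for plotting CDK2 against CDK4/6 with time as the parameter.
#'
#' @param cohort A `"cdk_cohort"`.
#' @param cell_ids Cells in the group (at least 10).
#' @param t_start,t_end Time window, hours.
#' @param thresholds Thresholds list (correction factor).
#' @param smooth_window Running-median window (default 3).
#' @return Tibble: `time_h`, `cdk46_med`, `cdk2_med`, `n`.
#' @export
phase_trajectory <- function(cohort, cell_ids, t_start = NULL, t_end = NULL,
                             thresholds = default_thresholds(),
                             smooth_window = 3) {
  if (length(cell_ids) < 10) {
    abort("need >= 10 cells in the group",
          class = "cdktrace_insufficient_data_error")
  }
  sm <- smooth_cohort(cohort, window = smooth_window)
  tr <- sm$traces |>
    dplyr::filter(.data$cell_id %in% cell_ids)
  if (!is.null(t_start)) tr <- dplyr::filter(tr, .data$time_h >= t_start)
  if (!is.null(t_end)) tr <- dplyr::filter(tr, .data$time_h <= t_end)
  tr$cdk46_corr <- corrected_cdk46(tr$cdk46_raw, tr$cdk2,
                                   thresholds$f_correction)
  tr |>
    dplyr::group_by(time_h = .data$time_h) |>
    dplyr::summarise(cdk46_med = median(.data$cdk46_corr, na.rm = TRUE),
                     cdk2_med = median(.data$cdk2, na.rm = TRUE),
                     n = sum(!is.na(.data$cdk46_corr)),
                     .groups = "drop")
}

#' Rb phospho-positive fraction by CDK4/6 class and time since anaphase
#'
#' Live-fixed style analysis: each cell carries a terminal Rb
#' phospho-S807/811 intensity (in the cohort's ground truth or supplied
#' separately) measured at fixation, and a time-since-anaphase at fixation.
#' Cells are classed `high`/`low` by their smoothed corrected CDK4/6
#' activity at the final frame, and the fraction above `rb_threshold` is
#' reported per (class, time bin).
#'
#' @param cohort A cycling `"cdk_cohort"` with `rb_phospho` in ground truth,
#'   or `rb_values` supplied.
#' @param rb_threshold Intensity threshold (e.g. from
#'   [bimodal_threshold()]).
#' @param time_bins_post_anaphase Increasing bin edges, hours since
#'   anaphase at fixation.
#' @param rb_values Optional tibble `cell_id`, `rb_phospho` overriding the
#'   ground truth.
#' @param thresholds Thresholds list.
#' @param smooth_window Running-median window (default 3).
#' @return Tibble: `class`, `bin_lo`, `bin_hi`, `bin_center`, `n`,
#'   `fraction_phospho`.
#' @export
fraction_rb_phospho_by_class <- function(cohort, rb_threshold,
                                         time_bins_post_anaphase,
                                         rb_values = NULL,
                                         thresholds = default_thresholds(),
                                         smooth_window = 3) {
  if (is.null(rb_values)) {
    gt <- cohort$ground_truth
    if (is.null(gt) || !"rb_phospho" %in% names(gt) ||
        all(is.na(gt$rb_phospho))) {
      abort("no Rb phospho values available (live-fixed data required)",
            class = "cdktrace_protocol_error")
    }
    rb_values <- dplyr::select(gt, "cell_id", "rb_phospho")
  }
  sm <- smooth_cohort(cohort, window = smooth_window)
  sm$traces$cdk46_corr <- corrected_cdk46(sm$traces$cdk46_raw,
                                          sm$traces$cdk2,
                                          thresholds$f_correction)
  per_cell <- sm$traces |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(
      t_end = max(.data$time_h),
      cdk46_end = .data$cdk46_corr[which.max(.data$time_h)],
      anaphase = if (any(.data$is_anaphase %in% TRUE))
        min(.data$time_h[.data$is_anaphase %in% TRUE]) else NA_real_,
      .groups = "drop") |>
    dplyr::left_join(rb_values, by = "cell_id") |>
    dplyr::filter(!is.na(.data$anaphase), !is.na(.data$rb_phospho)) |>
    dplyr::mutate(
      t_since_ana = .data$t_end - .data$anaphase,
      class = ifelse(.data$cdk46_end > thresholds$theta_cdk46,
                     "high", "low"),
      bin = cut(.data$t_since_ana, breaks = time_bins_post_anaphase,
                right = FALSE))
  edges <- time_bins_post_anaphase
  lv <- levels(per_cell$bin)
  per_cell |>
    dplyr::filter(!is.na(.data$bin)) |>
    dplyr::group_by(.data$class, .data$bin) |>
    dplyr::summarise(n = dplyr::n(),
                     fraction_phospho = mean(.data$rb_phospho >
                                               rb_threshold),
                     .groups = "drop") |>
    dplyr::mutate(bin_lo = edges[match(.data$bin, lv)],
                  bin_hi = edges[match(.data$bin, lv) + 1],
                  bin_center = (.data$bin_lo + .data$bin_hi) / 2) |>
    dplyr::select("class", "bin_lo", "bin_hi", "bin_center", "n",
                  "fraction_phospho")
}
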