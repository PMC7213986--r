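# Cell-fate classification from traces and event records.
#
# All classifiers are deterministic functions of (trace, events, thresholds).
# They operate on smoothed, corrected activities supplied by classify_cohort.

value_at <- function(values, times, t) {
  i <- which.min(abs(times - t))
  values[i]
}

classify_release_one <- function(df, rec, th) {
  # high iff an onset was detected and corrected CDK4/6 stays above theta
  # through t_apc_off (if detected) or the trace end
  if (is.na(rec$t_cdk46_on)) return(list(label = "low", t_delay = NA_real_))
  t_stop <- if (!is.na(rec$t_apc_off)) rec$t_apc_off else max(df$time_h)
  win <- df$time_h >= rec$t_cdk46_on & df$time_h <= t_stop
  vals <- df$cdk46_corr[win]
  persistent <- all(vals[!is.na(vals)] > th$theta_cdk46)
  list(label = if (persistent) "high" else "low", t_delay = NA_real_)
}

classify_postmitotic_one <- function(df, rec, th) {
  ana <- rec$t_anaphase_ref
  if (is.na(ana)) {
    abort("cell has no anaphase annotation",
          class = "cdktrace_protocol_error")
  }
  t_end <- max(df$time_h)
  truncated <- (t_end - ana) < th$t_check_late
  early <- df$time_h > ana & df$time_h <= ana + th$t_check_early
  vals <- df$cdk46_corr[early]
  high <- length(vals) > 0 && all(vals[!is.na(vals)] > th$theta_cdk46)
  if (high) {
    return(list(label = "high", t_delay = NA_real_, truncated = truncated))
  }
  # among non-high cells: delay iff an onset is found after the early window
  post <- df$time_h > ana + th$t_check_early
  if (sum(post) < 2) {
    return(list(label = "low", t_delay = NA_real_, truncated = truncated))
  }
  onset <- detect_onset(df$cdk46_corr[post], df$time_h[post],
                        th$theta_cdk46,
                        min(th$persistence_window,
                            max(df$time_h[post]) - min(df$time_h[post])))
  if (!is.na(onset)) {
    return(list(label = "delay", t_delay = onset - ana,
                truncated = truncated))
  }
  list(label = "low", t_delay = NA_real_, truncated = truncated)
}

classify_stress_one <- function(df, rec, th) {
  v_perturb <- value_at(df$cdk2, df$time_h, th$t_perturb)
  v_outcome <- value_at(df$cdk2, df$time_h, th$t_outcome)
  low <- (!is.na(v_outcome) && v_outcome < th$theta_cdk2) ||
    (!is.na(v_outcome) && !is.na(v_perturb) &&
       v_outcome < 0.8 * v_perturb)
  list(label = if (low) "low" else "inc", t_delay = NA_real_)
}

#' Is a cell eligible for stress-outcome analysis?
#'
#' Eligible cells had active CDK4/6 and CDK2 and a flat APC/C degron at the
#' time the stress was applied: the smoothed corrected CDK4/6 and CDK2
#' activities at `t_perturb` exceed their thresholds and no degron rise was
#' detected at or before `t_perturb`. Eligibility uses only the state at the
#' moment of treatment (not post-treatment persistence), matching a
#' selection made before the response unfolds.
#'
#' @param cohort A `"cdk_cohort"`.
#' @param records Event tibble from [detect_events()] (for the APC/C-off
#'   point); computed if `NULL`.
#' @param thresholds Thresholds list.
#' @param smooth_window Running-median window (default 3).
#' @return Tibble `cell_id`, `eligible`, `cdk2_at_perturb`.
#' @export
stress_eligible <- function(cohort, records = NULL,
                            thresholds = default_thresholds(),
                            smooth_window = 3) {
  tp <- thresholds$t_perturb
  if (is.null(records)) {
    records <- detect_events(cohort, thresholds, smooth_window)
  }
  sm <- smooth_cohort(cohort, window = smooth_window)
  sm$traces$cdk46_corr <- corrected_cdk46(sm$traces$cdk46_raw,
                                          sm$traces$cdk2,
                                          thresholds$f_correction)
  at_tp <- sm$traces |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(
      c46_at = value_at(.data$cdk46_corr, .data$time_h, tp),
      cdk2_at_perturb = value_at(.data$cdk2, .data$time_h, tp),
      .groups = "drop")
  apc_flat <- setNames(is.na(records$t_apc_off) | records$t_apc_off > tp,
                       records$cell_id)
  at_tp |>
    dplyr::mutate(eligible = .data$c46_at > thresholds$theta_cdk46 &
                    .data$cdk2_at_perturb > thresholds$theta_cdk2 &
                    unname(apc_flat[.data$cell_id])) |>
    dplyr::select("cell_id", "eligible", "cdk2_at_perturb")
}

#' Classify every cell in a cohort
#'
#' Applies the context-appropriate fate classifier to each cell:
#'
#' * `"quiescence_release"`: `high` iff a CDK4/6 onset was detected and
#'   corrected CDK4/6 stays above threshold through the APC/C-off point or
#'   the trace end (persistent activation); otherwise `low`.
#' * `"mitotic_exit"`: `high` iff corrected CDK4/6 exceeds threshold at every
#'   unmasked frame within 2 h after anaphase; among the rest, `delay` iff a
#'   sustained onset occurs later (with `t_delay` = onset minus anaphase),
#'   else `low` (below threshold at the 2 h and 10 h checks). Cells with
#'   less than 10 h of post-anaphase recording carry `truncated = TRUE`.
#' * `"stress_outcome"`: `low` iff CDK2 at the outcome time is below the
#'   CDK2 threshold or has declined by more than 20% from its value when the
#'   stress was applied; otherwise `inc`. Only cells satisfying
#'   [stress_eligible()] are classified; the rest get `NA` labels.
#'
#' @param cohort A `"cdk_cohort"`.
#' @param records Event tibble from [detect_events()]; computed if `NULL`.
#' @param context `"quiescence_release"`, `"mitotic_exit"` or
#'   `"stress_outcome"`; defaults to a context matching the cohort protocol
#'   and perturbation.
#' @param thresholds Thresholds list.
#' @param smooth_window Running-median window (default 3).
#' @return Tibble with `cell_id`, `context`, `label`, `t_delay` (and
#'   `truncated` for mitotic exit; `eligible` for stress outcomes).
#' @export
classify_cohort <- function(cohort, records = NULL,
                            context = NULL,
                            thresholds = default_thresholds(),
                            smooth_window = 3) {
  if (is.null(context)) {
    context <- if (!is.null(cohort$perturbation) &&
                   cohort$perturbation$kind == "stress") "stress_outcome"
    else if (cohort$protocol == "cycling") "mitotic_exit"
    else "quiescence_release"
  }
  context <- match.arg(context, c("quiescence_release", "mitotic_exit",
                                  "stress_outcome"))
  if (is.null(records)) {
    records <- detect_events(cohort, thresholds, smooth_window)
  }
  sm <- smooth_cohort(cohort, window = smooth_window)
  sm$traces$cdk46_corr <- corrected_cdk46(sm$traces$cdk46_raw,
                                          sm$traces$cdk2,
                                          thresholds$f_correction)
  traces_by_cell <- split(sm$traces, sm$traces$cell_id)
  recs_by_cell <- split(records, records$cell_id)

  elig <- if (context == "stress_outcome") {
    e <- stress_eligible(cohort, records, thresholds, smooth_window)
    setNames(e$eligible, e$cell_id)
  } else NULL

  rows <- purrr::map(names(traces_by_cell), function(id) {
    df <- traces_by_cell[[id]]
    rec <- recs_by_cell[[id]]
    out <- switch(
      context,
      quiescence_release = classify_release_one(df, rec, thresholds),
      mitotic_exit = classify_postmitotic_one(df, rec, thresholds),
      stress_outcome = {
        if (isTRUE(elig[[id]])) classify_stress_one(df, rec, thresholds)
        else list(label = NA_character_, t_delay = NA_real_)
      })
    tibble::tibble(cell_id = id, context = context, label = out$label,
                   t_delay = out$t_delay,
                   truncated = out$truncated %||% NA,
                   eligible = if (is.null(elig)) NA else
                     isTRUE(elig[[id]]))
  })
  dplyr::bind_rows(rows)
}

#' Bimodal threshold from a two-component Gaussian mixture
#'
#' Fits a 2-component Gaussian mixture to log-transformed intensities (as
#' used for Rb phospho-S807/811 immunofluorescence, which is bimodal in
#' cycling populations) and returns the equal-posterior boundary between the
#' components, back-transformed to the intensity scale. When the mixture fit
#' is degenerate the inter-mode minimum of a kernel density is used; when
#' the two components are closer than one pooled standard deviation the data
#' are effectively unimodal and the global median is returned with a
#' warning.
#'
#' @param values Positive intensity values, at least 50.
#' @return Scalar threshold on the intensity scale.
#' @export
bimodal_threshold <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 50) {
    abort("need at least 50 values to set a bimodal threshold",
          class = "cdktrace_insufficient_data_error")
  }
  if (any(values <= 0)) {
    abort("intensities must be positive for log transformation",
          class = "cdktrace_parameter_error")
  }
  lv <- log(values)
  if (stats::sd(lv) < 1e-12) {
    warn("degenerate (constant) intensity distribution; returning median")
    return(stats::median(values))
  }
  fit <- tryCatch(
    suppressWarnings(mclust::Mclust(lv, G = 2, modelNames = "V",
                                    verbose = FALSE)),
    error = function(e) NULL)
  if (!is.null(fit) && !is.null(fit$parameters)) {
    mu <- fit$parameters$mean
    sig <- sqrt(fit$parameters$variance$sigmasq)
    if (length(sig) == 1) sig <- rep(sig, 2)
    pro <- fit$parameters$pro
    pooled <- sqrt(mean(sig^2))
    if (abs(diff(mu)) < pooled) {
      warn("mixture components within one pooled sd; returning median")
      return(stats::median(values))
    }
    lo <- min(mu); hi <- max(mu)
    post_diff <- function(x) {
      d <- pro[1] * dnorm(x, mu[1], sig[1]) -
        pro[2] * dnorm(x, mu[2], sig[2])
      d
    }
    b <- tryCatch(stats::uniroot(post_diff, c(lo, hi))$root,
                  error = function(e) NA_real_)
    if (!is.na(b)) return(exp(b))
  }
  # fallback: inter-mode minimum of the kernel density
  dens <- density(lv)
  dy <- dens$y
  peaks <- which(diff(sign(diff(dy))) == -2) + 1
  if (length(peaks) >= 2) {
    p1 <- peaks[which.max(dy[peaks])]
    p2 <- peaks[order(dy[peaks], decreasing = TRUE)][2]
    rng <- sort(c(p1, p2))
    valley <- rng[1] + which.min(dy[rng[1]:rng[2]]) - 1
    return(exp(dens$x[valley]))
  }
  warn("no clear bimodality in kernel density; returning median")
  stats::median(values)
}

#' Two-component bimodality decision
#'
#' A distribution is called bimodal when (i) a 2-component Gaussian mixture
#' is preferred over 1 component by BIC and (ii) the data's kernel density
#' actually shows two modes with a genuine dip between them (the valley is
#' below `dip_ratio` of the lower of the two peaks). BIC alone detects any
#' true mixture at large n even when the resulting density has a single
#' mode, so the dip requirement is what distinguishes a visibly bimodal
#' histogram from a merely heterogeneous one.
#'
#' @param values Numeric values.
#' @param dip_ratio Maximum valley-to-lower-peak density ratio (default
#'   0.9: the dip must cut at least 10% below the lower peak).
#' @param min_peak Peaks below this fraction of the tallest peak are
#'   ignored as tail ripples (default 0.1).
#' @return `TRUE`/`FALSE`, with attributes `bic_pref_2`, `n_modes` and
#'   `valley_ratio`.
#' @export
is_bimodal <- function(values, dip_ratio = 0.9, min_peak = 0.1) {
  values <- values[!is.na(values)]
  if (length(values) < 50 || stats::sd(values) < 1e-12) return(FALSE)
  b <- suppressWarnings(mclust::mclustBIC(values, G = 1:2,
                                          modelNames = "V", verbose = FALSE))
  bic1 <- b["1", "V"]; bic2 <- b["2", "V"]
  pref2 <- is.finite(bic2) && (!is.finite(bic1) || bic2 > bic1)
  dens <- density(values)
  y <- dens$y
  pk <- which(diff(sign(diff(y))) == -2) + 1
  pk <- pk[y[pk] >= min_peak * max(y)]
  vr <- NA_real_
  if (length(pk) >= 2) {
    top2 <- pk[order(y[pk], decreasing = TRUE)][1:2]
    rng <- sort(top2)
    valley <- min(y[rng[1]:rng[2]])
    vr <- valley / min(y[top2])
  }
  out <- isTRUE(pref2) && length(pk) >= 2 && isTRUE(vr < dip_ratio)
  attr(out, "bic_pref_2") <- pref2
  attr(out, "n_modes") <- length(pk)
  attr(out, "valley_ratio") <- vr
  out
}
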