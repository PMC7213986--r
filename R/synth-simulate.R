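# Synthetic dual-reporter cohort generator.
#
# Latent (noiseless) signals are piecewise-linear/saturating kinetic shapes;
# the observed raw CDK4/6 reporter is composed as
#   cdk46_raw = corrected CDK4/6 + f_true * CDK2 + noise,
# mirroring the additive CDK2 cross-contribution of the physical reporter.
# Ground-truth event times are threshold crossings of the latent signals,
# snapped to the sampling grid.

time_grid <- function(params) {
  nt <- floor(params$duration / params$dt + 1e-9) + 1
  (seq_len(nt) - 1) * params$dt
}

# inverse-CDF truncated normal; degenerates gracefully at sd = 0
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  if (sd <= 0) return(rep(mean, n))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

draw_cell_params <- function(params, n) {
  tibble::tibble(
    plateau = rtrunc_norm(n, params$plateau_cdk46, params$plateau_sd,
                          params$plateau_cdk46 - 2.5 * params$plateau_sd,
                          params$plateau_cdk46 + 2.5 * params$plateau_sd),
    slope_cdk2 = rtrunc_norm(n, params$cdk2_slope, params$cdk2_slope_sd,
                             max(1e-6, params$cdk2_slope -
                                   2.5 * params$cdk2_slope_sd),
                             params$cdk2_slope + 2.5 * params$cdk2_slope_sd),
    baseline_cdk2 = rtrunc_norm(n, params$cdk2_baseline,
                                params$cdk2_baseline_sd,
                                params$cdk2_baseline -
                                  2.2 * params$cdk2_baseline_sd,
                                params$cdk2_baseline +
                                  2.2 * params$cdk2_baseline_sd)
  )
}

first_time_at_or_above <- function(value, time, theta) {
  i <- which(value >= theta)
  if (length(i) == 0) NA_real_ else time[min(i)]
}

# observed = latent composition + iid Gaussian noise, clipped at zero.
# The degron channel sits on a positive background (autofluorescence):
# without it, clipping at zero turns baseline noise into a half-normal
# whose scale cannot be estimated from the data.
compose_observed <- function(latent, f_true, noise_sd,
                             degron_background = 0.2) {
  nr <- nrow(latent)
  latent |>
    dplyr::mutate(
      cdk46_raw = pmax(.data$cdk46_true + f_true * .data$cdk2_true +
                         rnorm(nr, 0, noise_sd), 0),
      cdk2 = pmax(.data$cdk2_true + rnorm(nr, 0, noise_sd), 0),
      apc_degron = pmax(degron_background + .data$apc_true +
                          rnorm(nr, 0, noise_sd), 0)
    )
}

annotate_truth <- function(latent, thresholds, from = NULL) {
  # threshold crossings of the latent signals, at or after the per-cell
  # anchor `from` (anaphase for cycling cohorts)
  latent |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(
      true_t_cdk46_on = {
        keep <- if (is.null(from)) rep(TRUE, dplyr::n()) else
          .data$time_h >= .data$from_t
        first_time_at_or_above(.data$cdk46_true[keep], .data$time_h[keep],
                               thresholds$theta_cdk46)
      },
      true_t_cdk2_on = {
        keep <- if (is.null(from)) rep(TRUE, dplyr::n()) else
          .data$time_h >= .data$from_t
        first_time_at_or_above(.data$cdk2_true[keep], .data$time_h[keep],
                               thresholds$theta_cdk2)
      },
      true_t_apc_off = {
        keep <- if (is.null(from)) rep(TRUE, dplyr::n()) else
          .data$time_h >= .data$from_t
        first_time_at_or_above(.data$apc_true[keep], .data$time_h[keep],
                               1e-12)
      },
      .groups = "drop"
    )
}

#' Simulate a quiescence-release cohort
#'
#' Cells are serum-starved then mitogen-released at time zero. With
#' probability `p_activate` a cell activates: corrected CDK4/6 rises rapidly
#' from baseline to its plateau after a uniform 5-13 h delay, CDK2 ramps
#' gradually from its elevated baseline starting `cdk2_lag` after the CDK4/6
#' ramp, and the APC/C degron starts accumulating once CDK2 crosses
#' `apc_trigger_cdk2`. Non-activating cells stay at baseline throughout,
#' keeping the degron flat. The observed raw CDK4/6 reporter is the corrected
#' activity plus `f_true` times CDK2 plus frame noise.
#'
#' @param params A [generator_params()].
#' @param thresholds Thresholds used to annotate ground-truth event times
#'   (threshold crossings of the noiseless signals).
#' @return A `"cdk_cohort"` with `ground_truth` and `latent` populated.
#' @examples
#' co <- simulate_quiescence_release(generator_params(n_cells = 5, seed = 1))
#' co
#' @export
simulate_quiescence_release <- function(params = generator_params(),
                                        thresholds = default_thresholds()) {
  validate_generator_params(params)
  if (params$duration < params$delay_range[2]) {
    warn(paste0("duration (", params$duration, " h) is shorter than the ",
                "activation delay upper bound (", params$delay_range[2],
                " h); late-activating cells are flagged as truncated"))
  }
  set.seed(params$seed)
  n <- params$n_cells
  tgrid <- time_grid(params)
  nt <- length(tgrid)
  ids <- sprintf("cell_%04d", seq_len(n))

  cp <- draw_cell_params(params, n)
  cp$activate <- runif(n) < params$p_activate
  cp$delay <- runif(n, params$delay_range[1], params$delay_range[2])
  cp$cell_id <- ids

  latent <- tidyr::expand_grid(cell_id = ids, time_h = tgrid) |>
    dplyr::left_join(cp, by = "cell_id") |>
    dplyr::mutate(
      cdk46_true = ifelse(
        .data$activate,
        params$baseline_cdk46 + (.data$plateau - params$baseline_cdk46) *
          pmin(pmax((.data$time_h - .data$delay) / params$rise_time_cdk46,
                    0), 1),
        params$baseline_cdk46),
      cdk2_true = ifelse(
        .data$activate,
        pmin(.data$baseline_cdk2 + .data$slope_cdk2 *
               pmax(.data$time_h - (.data$delay + params$cdk2_lag), 0),
             params$cdk2_max),
        .data$baseline_cdk2)
    )
  # degron accumulation begins at the grid time CDK2 reaches the trigger
  apc_start <- latent |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(
      t_apc_start = first_time_at_or_above(.data$cdk2_true, .data$time_h,
                                           params$apc_trigger_cdk2),
      .groups = "drop")
  latent <- latent |>
    dplyr::left_join(apc_start, by = "cell_id") |>
    dplyr::mutate(
      apc_true = ifelse(is.na(.data$t_apc_start), 0,
                        params$degron_rate *
                          pmax(.data$time_h - .data$t_apc_start, 0)))

  truth_times <- annotate_truth(latent, thresholds)
  gt <- cp |>
    dplyr::left_join(truth_times, by = "cell_id") |>
    dplyr::mutate(
      true_fate = ifelse(.data$activate, "high", "low"),
      true_t_cdk46_on = ifelse(.data$activate, .data$true_t_cdk46_on,
                               NA_real_),
      true_t_cdk2_on = ifelse(.data$activate, .data$true_t_cdk2_on,
                              NA_real_),
      responded_to_stress = NA,
      truncated = .data$activate &
        (is.na(.data$true_t_cdk46_on) | is.na(.data$true_t_cdk2_on) |
           is.na(.data$true_t_apc_off)),
      anaphase_time = NA_real_,
      rb_phospho = NA_real_,
      t_delay_true = NA_real_
    ) |>
    dplyr::select("cell_id", "true_fate", "true_t_cdk46_on",
                  "true_t_cdk2_on", "true_t_apc_off", "responded_to_stress",
                  "truncated", "anaphase_time", "rb_phospho", "t_delay_true",
                  "delay", "plateau", "slope_cdk2", "baseline_cdk2")

  latent <- latent |>
    dplyr::select("cell_id", "time_h", "cdk46_true", "cdk2_true", "apc_true")
  traces <- compose_observed(latent, params$f_true, params$noise_sd,
                             params$degron_background) |>
    dplyr::mutate(is_anaphase = FALSE, treatment = "none", dose = 0) |>
    dplyr::select("cell_id", "time_h", "cdk46_raw", "cdk2", "apc_degron",
                  "is_anaphase", "treatment", "dose")

  new_cohort(traces, protocol = "quiescence_release",
             t_zero_meaning = "mitogen release",
             ground_truth = gt, latent = latent, params = params)
}

#' Simulate an asynchronously cycling cohort aligned on mitosis
#'
#' Every cell passes through one annotated anaphase (uniform over
#' `anaphase_window`). Its post-mitotic fate is drawn from
#' `mitotic_fate_probs`: `high` cells keep corrected CDK4/6 at plateau from
#' anaphase and ramp CDK2 immediately; `low` cells drop both to baseline for
#' the remainder of the recording; `delay` cells spend a transient G0 of
#' uniform `delay_fate_range` hours at baseline and then re-run the
#' quiescence-release kinetics. A terminal Rb phospho-S807/811 intensity is
#' drawn per cell from the high mixture component iff the latent corrected
#' CDK4/6 is above the activity threshold at the final frame (live-fixed
#' emulation).
#'
#' @inheritParams simulate_quiescence_release
#' @return A `"cdk_cohort"` with anaphase annotations, `ground_truth`
#'   (including `rb_phospho` and `t_delay_true`) and `latent`.
#' @export
simulate_cycling <- function(params = generator_params(),
                             thresholds = default_thresholds()) {
  validate_generator_params(params)
  set.seed(params$seed)
  n <- params$n_cells
  tgrid <- time_grid(params)
  ids <- sprintf("cell_%04d", seq_len(n))
  dt <- params$dt

  cp <- draw_cell_params(params, n)
  fates <- names(params$mitotic_fate_probs)
  if (is.null(fates)) fates <- c("high", "low", "delay")
  cp$fate <- sample(fates, n, replace = TRUE,
                    prob = params$mitotic_fate_probs)
  a_raw <- runif(n, params$anaphase_window[1],
                 min(params$anaphase_window[2], params$duration - dt))
  cp$anaphase <- pmin(pmax(round(a_raw / dt) * dt, dt),
                      params$duration - dt)
  cp$g0 <- runif(n, params$delay_fate_range[1], params$delay_fate_range[2])
  cp$cell_id <- ids

  latent <- tidyr::expand_grid(cell_id = ids, time_h = tgrid) |>
    dplyr::left_join(cp, by = "cell_id") |>
    dplyr::mutate(
      rise_start = dplyr::case_when(
        .data$fate == "high" ~ .data$anaphase,
        .data$fate == "delay" ~ .data$anaphase + .data$g0,
        TRUE ~ Inf),
      cdk46_true = dplyr::case_when(
        .data$time_h < .data$anaphase ~ .data$plateau,
        .data$fate == "high" ~ .data$plateau,
        .data$fate == "low" ~ params$baseline_cdk46,
        TRUE ~ params$baseline_cdk46 +
          (.data$plateau - params$baseline_cdk46) *
          pmin(pmax((.data$time_h - .data$rise_start) /
                      params$rise_time_cdk46, 0), 1)),
      ramp_start = dplyr::case_when(
        .data$fate == "high" ~ .data$anaphase,
        .data$fate == "delay" ~ .data$rise_start + params$cdk2_lag,
        TRUE ~ Inf),
      cdk2_true = pmin(.data$baseline_cdk2 + .data$slope_cdk2 *
                         pmax(.data$time_h - .data$ramp_start, 0),
                       params$cdk2_max)
    )
  apc_start <- latent |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(
      t_apc_start = {
        post <- .data$time_h > .data$anaphase
        first_time_at_or_above(.data$cdk2_true[post], .data$time_h[post],
                               params$apc_trigger_cdk2)
      },
      .groups = "drop")
  latent <- latent |>
    dplyr::left_join(apc_start, by = "cell_id") |>
    dplyr::mutate(
      apc_true = ifelse(is.na(.data$t_apc_start), 0,
                        params$degron_rate *
                          pmax(.data$time_h - .data$t_apc_start, 0)),
      from_t = .data$anaphase)

  truth_times <- annotate_truth(latent, thresholds, from = "anaphase")

  # terminal corrected CDK4/6 state drives the Rb phospho mixture component
  terminal <- latent |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(on_at_end = dplyr::last(.data$cdk46_true) >=
                       thresholds$theta_cdk46, .groups = "drop")
  rb <- terminal |>
    dplyr::mutate(rb_phospho = exp(rnorm(
      dplyr::n(),
      mean = ifelse(.data$on_at_end, params$rb_meanlog[["high"]],
                    params$rb_meanlog[["low"]]),
      sd = params$rb_sdlog)))

  gt <- cp |>
    dplyr::left_join(truth_times, by = "cell_id") |>
    dplyr::left_join(dplyr::select(rb, "cell_id", "rb_phospho"),
                     by = "cell_id") |>
    dplyr::mutate(
      true_fate = .data$fate,
      t_delay_true = ifelse(.data$fate == "delay", .data$g0, NA_real_),
      true_t_cdk46_on = ifelse(.data$fate == "low", NA_real_,
                               .data$true_t_cdk46_on),
      true_t_cdk2_on = ifelse(.data$fate == "low", NA_real_,
                              .data$true_t_cdk2_on),
      responded_to_stress = NA,
      truncated = .data$anaphase + thresholds$t_check_late >
        params$duration,
      anaphase_time = .data$anaphase
    ) |>
    dplyr::select("cell_id", "true_fate", "true_t_cdk46_on",
                  "true_t_cdk2_on", "true_t_apc_off", "responded_to_stress",
                  "truncated", "anaphase_time", "rb_phospho", "t_delay_true",
                  "plateau", "slope_cdk2", "baseline_cdk2")

  latent <- latent |>
    dplyr::select("cell_id", "time_h", "cdk46_true", "cdk2_true", "apc_true")
  traces <- compose_observed(latent, params$f_true, params$noise_sd,
                             params$degron_background) |>
    dplyr::left_join(dplyr::select(cp, "cell_id", "anaphase"),
                     by = "cell_id") |>
    dplyr::mutate(is_anaphase = abs(.data$time_h - .data$anaphase) <
                    params$dt / 2,
                  treatment = "none", dose = 0) |>
    dplyr::select("cell_id", "time_h", "cdk46_raw", "cdk2", "apc_degron",
                  "is_anaphase", "treatment", "dose")

  new_cohort(traces, protocol = "cycling",
             t_zero_meaning = "recording start",
             ground_truth = gt, latent = latent, params = params)
}
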