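#' Parameters of the synthetic cohort generator
#'
#' Defines the kinetic and statistical structure of simulated dual-reporter
#' cohorts. Defaults emulate the study conditions of the imaging
#' experiments the package analyses: 12-min sampling (`dt = 0.2` h),
#' quiescence-released cells that activate CDK4/6 rapidly (rise time 1 h to a
#' plateau near 0.9) after a long variable delay (uniform 5-13 h) with
#' probability `p_activate` (default 0.54), a gradual CDK2 ramp starting
#' `cdk2_lag` after CDK4/6-on from an elevated baseline (~0.5), APC/C-degron
#' accumulation once CDK2 crosses `apc_trigger_cdk2` (1.0), trimodal mitotic
#' exit fates (high / low / delay with a 2-9 h transient G0 for delay cells),
#' additive CDK2 contamination of the raw CDK4/6 reporter with fraction
#' `f_true` (0.35), and i.i.d. Gaussian frame noise.
#'
#' Per-cell heterogeneity (`plateau_sd`, `cdk2_baseline_sd`, `cdk2_slope_sd`)
#' spreads the population histograms the way real single-cell data are
#' spread; draws are truncated at mean +/- 2.5 sd (2.2 sd for the CDK2
#' baseline) so threshold semantics stay unambiguous — at the defaults,
#' plateaus lie in \[0.8, 1\] and CDK2 baselines stay below the 0.76
#' activation threshold.
#'
#' @param n_cells Number of cells to simulate.
#' @param dt Sampling interval, hours (default 0.2 = 12 min).
#' @param duration Recording length, hours.
#' @param p_activate Probability a quiescence-released cell activates CDK4/6.
#' @param delay_range Uniform low/high (hours) of the CDK4/6 activation delay.
#' @param rise_time_cdk46 Hours for the rapid baseline-to-plateau rise.
#' @param plateau_cdk46,plateau_sd Mean and per-cell sd of the corrected
#'   CDK4/6 plateau.
#' @param baseline_cdk46 Corrected CDK4/6 baseline in quiescence.
#' @param cdk2_baseline,cdk2_baseline_sd Mean and per-cell sd of the CDK2
#'   baseline.
#' @param cdk2_lag Hours from CDK4/6-on (ramp start) to the CDK2 ramp start.
#' @param cdk2_slope,cdk2_slope_sd Mean and per-cell sd of the CDK2 ramp
#'   slope, activity/hour.
#' @param cdk2_max Cap on CDK2 activity late in the cycle.
#' @param apc_trigger_cdk2 CDK2 level at which degron accumulation begins.
#' @param degron_rate Degron accumulation rate, intensity/hour.
#' @param degron_background Constant background intensity of the degron
#'   channel (autofluorescence floor; default 0.2).
#' @param mitotic_fate_probs Named probabilities over `c(high, low, delay)`
#'   for the fate at mitotic exit.
#' @param delay_fate_range Uniform low/high (hours) of the transient
#'   low-CDK4/6 period of delay-fate cells.
#' @param anaphase_window Uniform low/high (hours) over which anaphase times
#'   fall in cycling simulations.
#' @param noise_sd Additive Gaussian sd per sampled value.
#' @param f_true CDK2 contamination fraction added to the raw CDK4/6 signal.
#' @param rb_meanlog,rb_sdlog Log-scale means (named `low`, `high`) and sd of
#'   the two Rb phospho-S807/811 intensity mixture components.
#' @param seed Integer seed; fixing it reproduces the cohort bit-identically.
#'
#' @return A validated list of class `"generator_params"`.
#' @export
generator_params <- function(n_cells = 100,
                             dt = 0.2,
                             duration = 24,
                             p_activate = 0.54,
                             delay_range = c(5, 13),
                             rise_time_cdk46 = 1.0,
                             plateau_cdk46 = 0.9,
                             plateau_sd = 0.04,
                             baseline_cdk46 = 0.2,
                             cdk2_baseline = 0.5,
                             cdk2_baseline_sd = 0.10,
                             cdk2_lag = 1.0,
                             cdk2_slope = 0.11,
                             cdk2_slope_sd = 0.02,
                             cdk2_max = 2.5,
                             apc_trigger_cdk2 = 1.0,
                             degron_rate = 1.0,
                             degron_background = 0.2,
                             mitotic_fate_probs = c(high = 0.5, low = 0.2,
                                                    delay = 0.3),
                             delay_fate_range = c(2, 9),
                             anaphase_window = c(1, 13),
                             noise_sd = 0.03,
                             f_true = 0.35,
                             rb_meanlog = c(low = 0, high = log(10)),
                             rb_sdlog = 0.3,
                             seed = 1L) {
  p <- as.list(environment())
  validate_generator_params(p)
  structure(p, class = "generator_params")
}

validate_generator_params <- function(p) {
  chk <- function(cond, msg) if (!isTRUE(cond)) {
    abort(msg, class = "cdktrace_parameter_error")
  }
  chk(p$n_cells >= 1, "n_cells must be >= 1")
  chk(p$dt > 0, "dt must be positive")
  chk(p$duration > p$dt, "duration must exceed dt")
  chk(p$p_activate >= 0 && p$p_activate <= 1,
      "p_activate must be a probability in [0, 1]")
  chk(length(p$delay_range) == 2 && p$delay_range[1] <= p$delay_range[2],
      "delay_range must be an increasing (low, high) pair")
  chk(p$rise_time_cdk46 > 0, "rise_time_cdk46 must be positive")
  chk(p$rise_time_cdk46 < p$delay_range[1],
      "rise_time_cdk46 must be smaller than the delay_range low bound")
  chk(all(p$mitotic_fate_probs >= 0) && all(p$mitotic_fate_probs <= 1),
      "mitotic_fate_probs must be probabilities in [0, 1]")
  chk(abs(sum(p$mitotic_fate_probs) - 1) <= 1e-9,
      "mitotic_fate_probs must sum to 1")
  chk(length(p$delay_fate_range) == 2 &&
        p$delay_fate_range[1] <= p$delay_fate_range[2],
      "delay_fate_range must be an increasing (low, high) pair")
  chk(p$noise_sd >= 0, "noise_sd must be nonnegative")
  chk(p$f_true >= 0 && p$f_true <= 1, "f_true must lie in [0, 1]")
  chk(p$plateau_cdk46 > p$baseline_cdk46,
      "plateau_cdk46 must exceed baseline_cdk46")
  chk(p$cdk2_slope > 0, "cdk2_slope must be positive")
  chk(p$apc_trigger_cdk2 > 0, "apc_trigger_cdk2 must be positive")
  chk(p$degron_rate > 0, "degron_rate must be positive")
  chk(p$degron_background >= 0, "degron_background must be >= 0")
  invisible(p)
}

#' Specification of an acute perturbation
#'
#' Describes a treatment applied at `t_add` hours to a synthetic cohort:
#' a CDK4/6-selective inhibitor (nulls the CDK4/6-specific signal, leaving
#' the CDK2 cross-contribution), a CDK2 inhibitor (suppresses CDK2 activity
#' and drops the raw CDK4/6 reporter by `cdk2_reduction`), or a stress that
#' inactivates CDK4/6 with a probability that decreases with the cell's CDK2
#' activity at the time of stress (logistic in CDK2), followed by CDK2
#' inactivation after `cdk46_to_cdk2_lag` hours (0 for NaCl-like osmotic
#' stress, where both fall together).
#'
#' @param kind `"cdk46_inhibitor"`, `"cdk2_inhibitor"` or `"stress"`.
#' @param t_add Hours at which the perturbation is added (default 11).
#' @param residual_fraction Fraction of the corrected CDK4/6 plateau
#'   surviving a CDK4/6 inhibitor (default 0).
#' @param cdk2_reduction Fractional drop of the raw CDK4/6 reporter under a
#'   CDK2 inhibitor (default 0.15, inside the observed 10-20% range).
#' @param exit_logistic Named `c(midpoint, steepness)` of the decreasing
#'   logistic exit probability as a function of CDK2 activity at `t_add`.
#' @param cdk46_to_cdk2_lag Hours between CDK4/6 and CDK2 inactivation in
#'   stress-responding cells (default 1; use 0 for NaCl-like stress).
#' @param decay_rate Exponential inactivation rate (1/h) of reporter
#'   activities in responding cells (default 2).
#' @param g1_cdk2_lag,g1_cdk2_decay Lag (h) and slow decay rate (1/h) of the
#'   CDK2 reversal in G1 cells after CDK4/6 inhibition.
#'
#' @return A validated list of class `"perturbation_spec"`.
#' @export
perturbation_spec <- function(kind = c("cdk46_inhibitor", "cdk2_inhibitor",
                                       "stress"),
                              t_add = 11,
                              residual_fraction = 0,
                              cdk2_reduction = 0.15,
                              exit_logistic = c(midpoint = 0.9,
                                                steepness = 10),
                              cdk46_to_cdk2_lag = 1,
                              decay_rate = 2,
                              g1_cdk2_lag = 1,
                              g1_cdk2_decay = 0.3) {
  if (length(kind) > 1) kind <- kind[1]
  if (!kind %in% c("cdk46_inhibitor", "cdk2_inhibitor", "stress")) {
    abort(paste0("unknown perturbation kind: ", kind),
          class = "cdktrace_parameter_error")
  }
  chk <- function(cond, msg) if (!isTRUE(cond)) {
    abort(msg, class = "cdktrace_parameter_error")
  }
  chk(t_add > 0, "t_add must be positive")
  chk(residual_fraction >= 0 && residual_fraction <= 1,
      "residual_fraction must lie in [0, 1]")
  chk(cdk2_reduction >= 0 && cdk2_reduction <= 1,
      "cdk2_reduction must lie in [0, 1]")
  chk(length(exit_logistic) == 2 && all(is.finite(exit_logistic)) &&
        exit_logistic[2] >= 0,
      "exit_logistic must be (midpoint, steepness) with steepness >= 0")
  chk(cdk46_to_cdk2_lag >= 0, "cdk46_to_cdk2_lag must be >= 0")
  chk(decay_rate > 0, "decay_rate must be positive")
  chk(g1_cdk2_lag >= 0 && g1_cdk2_decay >= 0,
      "g1 reversal lag and decay must be >= 0")
  structure(
    list(kind = kind, t_add = t_add, residual_fraction = residual_fraction,
         cdk2_reduction = cdk2_reduction,
         exit_logistic = c(midpoint = unname(exit_logistic[1]),
                           steepness = unname(exit_logistic[2])),
         cdk46_to_cdk2_lag = cdk46_to_cdk2_lag, decay_rate = decay_rate,
         g1_cdk2_lag = g1_cdk2_lag, g1_cdk2_decay = g1_cdk2_decay),
    class = "perturbation_spec"
  )
}

#' Stress exit probability as a function of CDK2 activity
#'
#' Decreasing logistic: `1 / (1 + exp(steepness * (cdk2 - midpoint)))`.
#'
#' @param cdk2 CDK2 activity at the time stress is applied.
#' @param spec A `"perturbation_spec"` of kind `"stress"`.
#' @return Exit probabilities in `[0, 1]`, nonincreasing in `cdk2`.
#' @export
stress_exit_probability <- function(cdk2, spec) {
  el <- spec$exit_logistic
  plogis(-(el[["steepness"]]) * (cdk2 - el[["midpoint"]]))
}
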