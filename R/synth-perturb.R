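# Acute perturbations of synthetic cohorts.
#
# Perturbations act on the latent (noiseless) signals and the observed
# traces are recomposed with fresh seeded noise, so the composition
# raw = corrected + f_true * CDK2 (+ noise) holds before and after t_add.

latent_value_at <- function(latent, col, t) {
  latent |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(value = stats::approx(.data$time_h, .data[[col]],
                                           xout = t, rule = 2)$y,
                     .groups = "drop")
}

#' Apply an acute perturbation to a synthetic cohort
#'
#' Modifies the cohort's latent signals according to the perturbation kind
#' and recomposes the observed traces (fresh seeded noise at the cohort's
#' noise level):
#'
#' * `cdk46_inhibitor` - the corrected CDK4/6 signal decays to
#'   `residual_fraction` of the cell's plateau within 2 frames of `t_add`;
#'   the observed raw reporter keeps the `f_true * CDK2` cross-contribution,
#'   which cannot be suppressed. Cells still in G1 (degron flat at `t_add`)
#'   hold CDK2 for `g1_cdk2_lag` hours and then slowly reverse toward
#'   baseline, and no longer enter S phase; cells already past G1/S continue
#'   unperturbed in CDK2 and degron.
#' * `cdk2_inhibitor` - CDK2 activity falls rapidly toward a floor chosen so
#'   the raw CDK4/6 reporter drops by `cdk2_reduction` of its value at
#'   `t_add`; the CDK4/6-specific signal is untouched. Cells that had not yet
#'   inactivated APC/C do not enter S phase.
#' * `stress` - every cell with a flat degron at `t_add` draws a cell-cycle
#'   exit from the decreasing logistic [stress_exit_probability()] evaluated
#'   at its CDK2 activity at `t_add`. Exiting cells inactivate CDK4/6 first
#'   (exponential decay toward baseline at `decay_rate`), with CDK2 held at
#'   its stress-time value for `cdk46_to_cdk2_lag` hours before decaying at
#'   the same rate; cells with a rising degron (post-G1/S) never exit.
#'   Ground truth gains `responded_to_stress`.
#'
#' @param cohort A synthetic `"cdk_cohort"` (must carry latent signals).
#' @param spec A [perturbation_spec()].
#' @return A perturbed `"cdk_cohort"`; `cohort$perturbation` records the
#'   spec and the `treatment` column of the traces records the kind.
#' @export
apply_perturbation <- function(cohort, spec) {
  if (!inherits(spec, "perturbation_spec")) {
    abort("spec must be a perturbation_spec()",
          class = "cdktrace_parameter_error")
  }
  if (is.null(cohort$latent) || is.null(cohort$ground_truth) ||
      is.null(cohort$params)) {
    abort("apply_perturbation requires a synthetic cohort with latent signals",
          class = "cdktrace_parameter_error")
  }
  span <- range(cohort$traces$time_h)
  if (spec$t_add < span[1] || spec$t_add > span[2]) {
    abort("t_add must fall within the recorded time span",
          class = "cdktrace_parameter_error")
  }
  params <- cohort$params
  latent <- cohort$latent
  gt <- cohort$ground_truth

  set.seed((params$seed + 104729L) %% .Machine$integer.max)

  v46 <- latent_value_at(latent, "cdk46_true", spec$t_add)
  v2 <- latent_value_at(latent, "cdk2_true", spec$t_add)
  cell <- gt |>
    dplyr::left_join(dplyr::rename(v46, c46_0 = "value"), by = "cell_id") |>
    dplyr::left_join(dplyr::rename(v2, cdk2_0 = "value"), by = "cell_id") |>
    dplyr::mutate(in_g1 = is.na(.data$true_t_apc_off) |
                    .data$true_t_apc_off > spec$t_add)

  if (spec$kind == "stress") {
    cell$p_exit <- ifelse(cell$in_g1,
                          stress_exit_probability(cell$cdk2_0, spec), 0)
    cell$exit <- runif(nrow(cell)) < cell$p_exit
  }

  lt <- latent |>
    dplyr::left_join(
      dplyr::select(cell, "cell_id", "in_g1", "c46_0", "cdk2_0",
                    dplyr::any_of("exit"), "baseline_cdk2", "plateau"),
      by = "cell_id")
  s <- pmax(lt$time_h - spec$t_add, 0)  # hours since perturbation
  post <- lt$time_h > spec$t_add

  if (spec$kind == "cdk46_inhibitor") {
    target <- spec$residual_fraction * lt$plateau
    frac <- pmin(s / (2 * params$dt), 1)  # full effect within 2 frames
    lt$cdk46_true <- ifelse(post,
                            lt$c46_0 + (target - lt$c46_0) * frac,
                            lt$cdk46_true)
    # G1 cells hold CDK2, then slowly reverse the steady increase
    s2 <- pmax(lt$time_h - spec$t_add - spec$g1_cdk2_lag, 0)
    rev2 <- ifelse(s2 > 0,
                   lt$baseline_cdk2 + (lt$cdk2_0 - lt$baseline_cdk2) *
                     exp(-spec$g1_cdk2_decay * s2),
                   lt$cdk2_0)
    lt$cdk2_true <- ifelse(post & lt$in_g1, rev2, lt$cdk2_true)
    lt$apc_true <- ifelse(lt$in_g1, 0, lt$apc_true)
    gt$true_t_apc_off[cell$in_g1] <- NA_real_
    # activations that had not happened by t_add are blocked
    gt$true_t_cdk46_on[!is.na(gt$true_t_cdk46_on) &
                         gt$true_t_cdk46_on > spec$t_add] <- NA_real_
    late2 <- cell$in_g1 & !is.na(gt$true_t_cdk2_on) &
      gt$true_t_cdk2_on > spec$t_add
    gt$true_t_cdk2_on[late2] <- NA_real_
  } else if (spec$kind == "cdk2_inhibitor") {
    floor2 <- if (params$f_true > 0) {
      raw0 <- lt$c46_0 + params$f_true * lt$cdk2_0
      pmax(lt$cdk2_0 - spec$cdk2_reduction * raw0 / params$f_true, 0)
    } else {
      lt$baseline_cdk2
    }
    lt$cdk2_true <- ifelse(post,
                           floor2 + (lt$cdk2_0 - floor2) * exp(-6 * s),
                           lt$cdk2_true)
    lt$apc_true <- ifelse(lt$in_g1, 0, lt$apc_true)
    gt$true_t_apc_off[cell$in_g1] <- NA_real_
    gt$true_t_cdk2_on[!is.na(gt$true_t_cdk2_on) &
                        gt$true_t_cdk2_on > spec$t_add] <- NA_real_
  } else { # stress
    dec <- exp(-spec$decay_rate * s)
    c46_exit <- params$baseline_cdk46 +
      (lt$c46_0 - params$baseline_cdk46) * dec
    lt$cdk46_true <- ifelse(post & lt$exit, c46_exit, lt$cdk46_true)
    s2 <- pmax(lt$time_h - spec$t_add - spec$cdk46_to_cdk2_lag, 0)
    cdk2_exit <- ifelse(s2 > 0,
                        lt$baseline_cdk2 + (lt$cdk2_0 - lt$baseline_cdk2) *
                          exp(-spec$decay_rate * s2),
                        lt$cdk2_0)
    lt$cdk2_true <- ifelse(post & lt$exit, cdk2_exit, lt$cdk2_true)
    lt$apc_true <- ifelse(lt$exit, 0, lt$apc_true)
    gt$responded_to_stress <- cell$exit
    gt$true_t_apc_off[cell$exit] <- NA_real_
    # events that had not happened by t_add never happen in exiting cells
    late46 <- cell$exit & !is.na(gt$true_t_cdk46_on) &
      gt$true_t_cdk46_on > spec$t_add
    gt$true_t_cdk46_on[late46] <- NA_real_
    late2 <- cell$exit & !is.na(gt$true_t_cdk2_on) &
      gt$true_t_cdk2_on > spec$t_add
    gt$true_t_cdk2_on[late2] <- NA_real_
  }

  new_latent <- lt |>
    dplyr::select("cell_id", "time_h", "cdk46_true", "cdk2_true", "apc_true")
  traces <- compose_observed(new_latent, params$f_true, params$noise_sd,
                             params$degron_background %||% 0.2) |>
    dplyr::left_join(
      dplyr::select(cohort$traces, "cell_id", "time_h", "is_anaphase"),
      by = c("cell_id", "time_h")) |>
    dplyr::mutate(treatment = spec$kind, dose = 1) |>
    dplyr::select("cell_id", "time_h", "cdk46_raw", "cdk2", "apc_degron",
                  "is_anaphase", "treatment", "dose")

  out <- cohort
  out$traces <- traces
  out$latent <- new_latent
  out$ground_truth <- gt
  out$perturbation <- spec
  validate_cohort(out)
  out
}
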