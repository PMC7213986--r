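#' Analysis thresholds and fixed constants
#'
#' Returns the set of fixed constants used throughout the analysis: activity
#' thresholds for calling CDK4/6 and CDK2 "on", the CDK2 level taken as the
#' S-phase range, the CDK2 cross-contribution fraction subtracted from the raw
#' CDK4/6 reporter, the post-anaphase checkpoint times used for fate
#' classification, onset persistence windows, and the perturbation/outcome
#' times of the stress protocol.
#'
#' All times are hours; activities are unitless cytoplasmic:nuclear reporter
#' ratios.
#'
#' @param theta_cdk46 Corrected CDK4/6 activity above which CDK4/6 is "on"
#'   (default 0.7).
#' @param theta_cdk2 CDK2 activity above which CDK2 is "on" (default 0.76).
#' @param theta_cdk2_sphase CDK2 activity characteristic of S phase
#'   (default 1.0).
#' @param f_correction Fraction of the CDK2 reporter signal subtracted from
#'   the raw CDK4/6 reporter to obtain corrected CDK4/6 activity
#'   (default 0.35).
#' @param t_check_early,t_check_late Hours after anaphase at which post-mitotic
#'   fates are checked (defaults 2 and 10).
#' @param persistence_window Hours a CDK4/6 threshold crossing must be
#'   sustained to count as an onset (default 2).
#' @param persistence_cdk2 Hours a CDK2 crossing must be sustained (default 1).
#' @param t_perturb Hours after mitogen release at which acute perturbations
#'   are applied (default 11).
#' @param t_outcome Hours at which the stress outcome is scored (default 15).
#' @param k_sigma Baseline-noise multiplier for APC/C-degron rise detection
#'   (default 3).
#'
#' @return A named list of class `"cdk_thresholds"`.
#' @examples
#' th <- default_thresholds()
#' th$theta_cdk46
#' @export
default_thresholds <- function(theta_cdk46 = 0.7,
                               theta_cdk2 = 0.76,
                               theta_cdk2_sphase = 1.0,
                               f_correction = 0.35,
                               t_check_early = 2,
                               t_check_late = 10,
                               persistence_window = 2,
                               persistence_cdk2 = 1,
                               t_perturb = 11,
                               t_outcome = 15,
                               k_sigma = 3) {
  th <- list(
    theta_cdk46 = theta_cdk46,
    theta_cdk2 = theta_cdk2,
    theta_cdk2_sphase = theta_cdk2_sphase,
    f_correction = f_correction,
    t_check_early = t_check_early,
    t_check_late = t_check_late,
    persistence_window = persistence_window,
    persistence_cdk2 = persistence_cdk2,
    t_perturb = t_perturb,
    t_outcome = t_outcome,
    k_sigma = k_sigma
  )
  validate_thresholds(th)
  structure(th, class = "cdk_thresholds")
}

validate_thresholds <- function(th) {
  num <- vapply(th, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                logical(1))
  if (!all(num)) {
    abort(paste0("thresholds must be finite scalars; offending field(s): ",
                 paste(names(th)[!num], collapse = ", ")))
  }
  pos <- vapply(th, function(x) x > 0, logical(1))
  if (!all(pos)) {
    abort(paste0("thresholds must be strictly positive; offending field(s): ",
                 paste(names(th)[!pos], collapse = ", ")))
  }
  if (th$t_check_early >= th$t_check_late) {
    abort("t_check_early must be smaller than t_check_late")
  }
  if (th$t_perturb >= th$t_outcome) {
    abort("t_perturb must be smaller than t_outcome")
  }
  if (th$f_correction > 1) {
    abort("f_correction must lie in [0, 1]")
  }
  invisible(th)
}

#' @export
print.cdk_thresholds <- function(x, ...) {
  cat("<cdk_thresholds>\n")
  for (nm in names(x)) cat(sprintf("  %-20s %g\n", nm, x[[nm]]))
  invisible(x)
}
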