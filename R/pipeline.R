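# Config-driven pipeline entry points: simulate -> analyze.
# Configs are plain lists or YAML files; every run writes a resolved copy of
# its configuration next to the outputs for provenance.

read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) {
      abort(paste0("config file not found: ", config),
            class = "cdktrace_io_error")
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) {
    abort("config must be a list or a YAML file path",
          class = "cdktrace_parameter_error")
  }
  config
}

resolve_thresholds <- function(config) {
  overrides <- config$thresholds
  if (!is.null(config$threshold_file)) {
    overrides <- utils::modifyList(yaml::read_yaml(config$threshold_file),
                                   overrides %||% list())
  }
  do.call(default_thresholds, overrides %||% list())
}

#' Simulate a cohort from a run configuration
#'
#' The configuration (list or YAML path) may contain blocks `generator`
#' (fields of [generator_params()]), `protocol`
#' (`"quiescence_release"`/`"cycling"`), `perturbation` (fields of
#' [perturbation_spec()]), a top-level `seed` (overrides the generator
#' seed), and `out` (output directory). Writes `cohort.csv`, the
#' ground-truth sidecar, and `resolved_config.yaml`.
#'
#' @param config List or YAML file path.
#' @param out Output directory (defaults to `config$out`).
#' @return The simulated `"cdk_cohort"`, invisibly; outputs on disk.
#' @export
run_simulate <- function(config, out = NULL) {
  config <- read_run_config(config)
  out <- out %||% config$out
  if (is.null(out)) {
    abort("no output directory: set `out`",
          class = "cdktrace_parameter_error")
  }
  gen <- config$generator %||% list()
  if (!is.null(config$seed)) gen$seed <- as.integer(config$seed)
  params <- do.call(generator_params, gen)
  protocol <- config$protocol %||% "quiescence_release"
  thresholds <- resolve_thresholds(config)
  cohort <- switch(protocol,
                   quiescence_release =
                     simulate_quiescence_release(params, thresholds),
                   cycling = simulate_cycling(params, thresholds),
                   abort(paste0("unknown protocol: ", protocol),
                         class = "cdktrace_parameter_error"))
  if (!is.null(config$perturbation)) {
    spec <- do.call(perturbation_spec, config$perturbation)
    cohort <- apply_perturbation(cohort, spec)
  }
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write_cohort(cohort, file.path(out, "cohort.csv"))
  resolved <- config
  resolved$generator <- params[setdiff(names(params), character(0))]
  resolved$generator$mitotic_fate_probs <-
    as.list(params$mitotic_fate_probs)
  resolved$generator$rb_meanlog <- as.list(params$rb_meanlog)
  resolved$thresholds <- unclass(thresholds)
  yaml::write_yaml(resolved, file.path(out, "resolved_config.yaml"))
  message(sprintf("simulated %d cells (protocol %s) -> %s",
                  n_cells(cohort), protocol, out))
  invisible(cohort)
}

#' Analyze a cohort from a run configuration
#'
#' Reads `cohort.csv` from `config$cohort` (or `<out>/cohort.csv`), detects
#' events, classifies fates, and writes `events.csv`, `fates.csv`,
#' `cumulative_curves.csv`, `summary.csv`, a stress bin table when the
#' config declares a stress perturbation, a correction fit when it declares
#' a CDK4/6 inhibitor, and `resolved_config.yaml`. Cell counts and filter
#' drops are logged via `message()`.
#'
#' @param config List or YAML file path.
#' @param out Output directory (defaults to `config$out`).
#' @return A list of the computed tables, invisibly.
#' @export
run_analyze <- function(config, out = NULL) {
  config <- read_run_config(config)
  out <- out %||% config$out
  if (is.null(out)) {
    abort("no output directory: set `out`",
          class = "cdktrace_parameter_error")
  }
  cohort_path <- config$cohort %||% file.path(out, "cohort.csv")
  protocol <- config$protocol %||% "quiescence_release"
  cohort <- read_cohort(cohort_path, protocol = protocol)
  if (n_cells(cohort) == 0) {
    abort("cohort is empty", class = "cdktrace_insufficient_data_error")
  }
  thresholds <- resolve_thresholds(config)
  smooth_window <- config$smooth_window %||% 3

  records <- detect_events(cohort, thresholds, smooth_window)
  message(sprintf("detected events for %d cells", nrow(records)))

  pert_kind <- config$perturbation$kind %||% NA_character_
  context <- if (identical(pert_kind, "stress")) "stress_outcome"
  else if (protocol == "cycling") "mitotic_exit" else "quiescence_release"
  fates <- classify_cohort(cohort, records, context = context,
                           thresholds = thresholds,
                           smooth_window = smooth_window)

  tgrid <- sort(unique(cohort$traces$time_h))
  rel <- if (protocol == "cycling") "t_anaphase_ref" else NULL
  curves <- dplyr::bind_rows(lapply(
    c("t_cdk46_on", "t_cdk2_on", "t_apc_off"),
    function(ev) cumulative_fraction(records, ev, tgrid, relative_to = rel)))

  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(records, file.path(out, "events.csv"), progress = FALSE)
  readr::write_csv(fates, file.path(out, "fates.csv"), progress = FALSE)
  readr::write_csv(curves, file.path(out, "cumulative_curves.csv"),
                   progress = FALSE)

  stress_bins <- NULL
  if (identical(pert_kind, "stress")) {
    cohort$perturbation <- do.call(perturbation_spec, config$perturbation)
    n_elig <- sum(stress_eligible(cohort, records, thresholds)$eligible)
    message(sprintf("%d of %d cells eligible at t_perturb = %g h",
                    n_elig, nrow(records), thresholds$t_perturb))
    stress_bins <- stress_exit_by_cdk2_bin(cohort, records, fates,
                                           thresholds)
    readr::write_csv(stress_bins, file.path(out, "stress_bins.csv"),
                     progress = FALSE)
  }

  fit <- NULL
  if (identical(pert_kind, "cdk46_inhibitor")) {
    cohort$perturbation <- do.call(perturbation_spec, config$perturbation)
    fit <- estimate_correction_factor(cohort,
                                      thresholds = thresholds,
                                      smooth_window = smooth_window)
    readr::write_csv(glance(fit), file.path(out, "correction_fit.csv"),
                     progress = FALSE)
  }

  counts <- fates |>
    dplyr::count(.data$context, .data$label) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n))
  summary_tbl <- counts
  if (!is.null(fit)) {
    summary_tbl <- dplyr::bind_rows(
      summary_tbl,
      tibble::tibble(context = "correction", label = "f_hat",
                     n = fit$n_points, fraction = fit$f_hat))
  }
  readr::write_csv(summary_tbl, file.path(out, "summary.csv"),
                   progress = FALSE)
  resolved <- config
  resolved$thresholds <- unclass(thresholds)
  yaml::write_yaml(resolved, file.path(out, "resolved_config.yaml"))
  message(sprintf("fate counts: %s",
                  paste(sprintf("%s=%d", counts$label, counts$n),
                        collapse = ", ")))
  invisible(list(records = records, fates = fates, curves = curves,
                 stress_bins = stress_bins, correction_fit = fit))
}
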