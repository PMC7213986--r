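#' Construct a cohort of single-cell reporter traces
#'
#' A cohort bundles a long-format track table (one row per cell per frame)
#' with experiment metadata and, for synthetic cohorts, the generator's
#' ground-truth labels and noiseless latent signals.
#'
#' The track table must have columns `cell_id`, `time_h`, `cdk46_raw`,
#' `cdk2`, `apc_degron`, `is_anaphase`, and optionally `treatment` and
#' `dose`. Activity columns may contain `NA` for masked (missing) samples;
#' every cell must sit on a uniform time grid with a common step.
#'
#' @param traces Tibble/data frame in the long track-table format.
#' @param protocol `"quiescence_release"` or `"cycling"`.
#' @param perturbation Optional [perturbation_spec()] describing an acute
#'   treatment applied to the cohort.
#' @param t_zero_meaning Free-text note on what time zero means
#'   (mitogen release or recording start).
#' @param ground_truth Optional per-cell tibble of generator labels
#'   (`cell_id`, `true_fate`, `true_t_cdk46_on`, `true_t_cdk2_on`,
#'   `true_t_apc_off`, `responded_to_stress`, ...).
#' @param latent Optional long tibble of noiseless latent signals
#'   (synthetic cohorts only; required by [apply_perturbation()]).
#' @param params Optional [generator_params()] the cohort was built from.
#'
#' @return An object of class `"cdk_cohort"`.
#' @export
new_cohort <- function(traces,
                       protocol = c("quiescence_release", "cycling"),
                       perturbation = NULL,
                       t_zero_meaning = "recording start",
                       ground_truth = NULL,
                       latent = NULL,
                       params = NULL) {
  protocol <- match.arg(protocol)
  traces <- tibble::as_tibble(traces)
  if (!"treatment" %in% names(traces)) traces$treatment <- "none"
  if (!"dose" %in% names(traces)) traces$dose <- 0
  cohort <- structure(
    list(
      traces = traces,
      protocol = protocol,
      perturbation = perturbation,
      t_zero_meaning = t_zero_meaning,
      ground_truth = ground_truth,
      latent = latent,
      params = params
    ),
    class = "cdk_cohort"
  )
  validate_cohort(cohort)
  cohort
}

trace_required_cols <- c("cell_id", "time_h", "cdk46_raw", "cdk2",
                         "apc_degron", "is_anaphase")

#' Validate cohort invariants
#'
#' Checks that the track table has the required columns, that each cell sits
#' on a strictly increasing uniform time grid (constant step within relative
#' tolerance 1e-6), that anaphase annotations fall inside the recorded span,
#' that no (cell, frame) pair is duplicated, and that ground truth (when
#' present) covers exactly the cells in the track table.
#'
#' @param cohort A `"cdk_cohort"`.
#' @param tol Relative tolerance on time-step uniformity.
#' @return The cohort, invisibly; errors describe the first violation found.
#' @export
validate_cohort <- function(cohort, tol = 1e-6) {
  tr <- cohort$traces
  missing_cols <- setdiff(trace_required_cols, names(tr))
  if (length(missing_cols) > 0) {
    abort(paste0("track table is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "cdktrace_schema_error")
  }
  if (nrow(tr) == 0) return(invisible(cohort))
  if (anyDuplicated(tr[c("cell_id", "time_h")]) > 0) {
    abort("duplicate (cell_id, time_h) rows in track table",
          class = "cdktrace_format_error")
  }
  by_cell <- split(tr$time_h, tr$cell_id)
  for (id in names(by_cell)) {
    tt <- sort(by_cell[[id]])
    if (length(tt) >= 2) {
      dts <- diff(tt)
      if (any(dts <= 0)) {
        abort(paste0("times not strictly increasing for cell ", id),
              class = "cdktrace_format_error")
      }
      dt <- stats::median(dts)
      if (any(abs(dts - dt) > tol * max(dt, 1))) {
        abort(paste0("non-uniform time grid for cell ", id),
              class = "cdktrace_format_error")
      }
    }
    ana <- tr$time_h[tr$cell_id == id & tr$is_anaphase %in% TRUE]
    if (length(ana) > 0 && (min(ana) < min(tt) || max(ana) > max(tt))) {
      abort(paste0("anaphase outside recorded span for cell ", id),
            class = "cdktrace_format_error")
    }
  }
  gt <- cohort$ground_truth
  if (!is.null(gt)) {
    ids <- unique(tr$cell_id)
    if (!setequal(gt$cell_id, ids) || anyDuplicated(gt$cell_id) > 0) {
      abort("ground_truth must cover exactly the cell_ids in traces",
            class = "cdktrace_format_error")
    }
  }
  invisible(cohort)
}

#' @export
print.cdk_cohort <- function(x, ...) {
  n <- length(unique(x$traces$cell_id))
  cat(sprintf("<cdk_cohort> %d cells, protocol = %s\n", n, x$protocol))
  if (!is.null(x$perturbation)) {
    cat(sprintf("  perturbation: %s at %g h\n",
                x$perturbation$kind, x$perturbation$t_add))
  }
  if (!is.null(x$ground_truth)) cat("  ground truth present\n")
  cat(sprintf("  t = 0: %s\n", x$t_zero_meaning))
  invisible(x)
}

#' Number of cells in a cohort
#' @param cohort A `"cdk_cohort"`.
#' @return Integer count of distinct cells.
#' @export
n_cells <- function(cohort) {
  length(unique(cohort$traces$cell_id))
}

#' Read a cohort from a long-format CSV track table
#'
#' Expects one row per (cell, frame) with columns `cell_id`, `time_h`,
#' `cdk46_raw`, `cdk2`, `apc_degron`, `is_anaphase` (and optionally
#' `treatment`, `dose`); rows may be in any order. Missing activity values
#' become masked samples (`NA`). If a sidecar file `<path>_ground_truth.csv`
#' exists it is read as the per-cell ground-truth table.
#'
#' @param path CSV file path.
#' @param schema Optional named character vector mapping the canonical column
#'   names to the names used in the file, e.g.
#'   `c(cell_id = "track_id", time_h = "t")`.
#' @param protocol Protocol label for the cohort.
#' @return A `"cdk_cohort"`.
#' @export
read_cohort <- function(path, schema = NULL,
                        protocol = c("quiescence_release", "cycling")) {
  protocol <- match.arg(protocol)
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "cdktrace_io_error")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(schema)) {
    for (canonical in names(schema)) {
      src <- schema[[canonical]]
      if (src %in% names(raw)) names(raw)[names(raw) == src] <- canonical
    }
  }
  missing_cols <- setdiff(trace_required_cols, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("track table is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "cdktrace_schema_error")
  }
  raw <- dplyr::mutate(
    raw,
    cell_id = as.character(.data$cell_id),
    is_anaphase = as.logical(.data$is_anaphase)
  )
  raw <- dplyr::arrange(raw, .data$cell_id, .data$time_h)
  gt_path <- sidecar_path(path)
  gt <- NULL
  if (file.exists(gt_path)) {
    gt <- readr::read_csv(gt_path, show_col_types = FALSE, progress = FALSE)
    gt <- dplyr::mutate(gt, cell_id = as.character(.data$cell_id))
  }
  new_cohort(raw, protocol = protocol, ground_truth = gt,
             t_zero_meaning = if (protocol == "quiescence_release")
               "mitogen release" else "recording start")
}

sidecar_path <- function(path) {
  sub("\\.csv$", "", path) |> paste0("_ground_truth.csv")
}

#' Write a cohort to a CSV track table
#'
#' Writes the long track table to `path`; when ground truth is present it is
#' written to the sidecar `<path>_ground_truth.csv`. Reading the files back
#' with [read_cohort()] reproduces the cohort up to floating-point
#' round-trip.
#'
#' @param cohort A `"cdk_cohort"`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    abort(paste0("directory does not exist: ", dir),
          class = "cdktrace_io_error")
  }
  tr <- dplyr::arrange(cohort$traces, .data$cell_id, .data$time_h)
  readr::write_csv(tr, path, progress = FALSE)
  if (!is.null(cohort$ground_truth)) {
    readr::write_csv(dplyr::arrange(cohort$ground_truth, .data$cell_id),
                     sidecar_path(path), progress = FALSE)
  }
  invisible(path)
}
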