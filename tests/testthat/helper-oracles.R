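# Independent oracles and small fixture builders shared across tests.

# Exhaustive window scan: for every index, test the full sustained-crossing
# condition, then take the earliest passing time. Independent of the
# implementation's early-exit loop.
bf_onset <- function(series, times, theta, persistence) {
  passing <- c()
  for (i in seq_along(times)) {
    if (is.na(series[i]) || series[i] <= theta) next
    in_win <- times >= times[i] & times <= times[i] + persistence
    vals <- series[in_win]
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0 || all(vals > theta)) {
      passing <- c(passing, times[i])
    }
  }
  if (length(passing) == 0) NA_real_ else min(passing)
}

# one-cell track table on a uniform grid
make_trace_tbl <- function(cell_id = "c1", times = seq(0, 24, by = 0.2),
                           cdk46_raw = NULL, cdk2 = NULL,
                           apc_degron = NULL, anaphase_at = numeric(0)) {
  n <- length(times)
  tibble::tibble(
    cell_id = cell_id,
    time_h = times,
    cdk46_raw = cdk46_raw %||% rep(0.3, n),
    cdk2 = cdk2 %||% rep(0.5, n),
    apc_degron = apc_degron %||% rep(0, n),
    is_anaphase = vapply(times, function(t)
      any(abs(t - anaphase_at) < 0.1), logical(1)),
    treatment = "none", dose = 0
  )
}

make_cohort <- function(..., protocol = "quiescence_release") {
  new_cohort(dplyr::bind_rows(...), protocol = protocol)
}

`%||%` <- rlang::`%||%`
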