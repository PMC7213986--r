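test_that("alignment shifts each cell so its anchor sits at time zero", {
  times <- seq(0, 10, by = 0.2)
  co <- make_cohort(
    make_trace_tbl("a", times, cdk46_raw = times, anaphase_at = 4),
    make_trace_tbl("b", times, cdk46_raw = times + 1, anaphase_at = 6),
    protocol = "cycling")
  al <- align_to_event(co, anchor_kind = "anaphase", channel = "cdk46_raw")
  expect_equal(unname(al$values["a", al$relative_times == 0]), 4)
  expect_equal(unname(al$values["b", al$relative_times == 0]), 7)
  # the overlap region holds both cells unmasked
  overlap <- al$relative_times >= -4 & al$relative_times <= 4
  expect_true(all(!is.na(al$values[, overlap])))
  # a single cell aligned at 4 h is the trace shifted by -4 h
  al1 <- align_to_event(make_cohort(
    make_trace_tbl("a", times, cdk46_raw = times, anaphase_at = 4),
    protocol = "cycling"), anchor_kind = "anaphase", channel = "cdk46_raw")
  expect_equal(al1$relative_times, times - 4)
  expect_equal(unname(al1$values["a", ]), times)
})

test_that("aligned high- and low-fate rows separate at anaphase + 2 h", {
  co <- simulate_cycling(generator_params(n_cells = 300, seed = 41))
  th <- default_thresholds()
  al <- align_to_event(co, anchor_kind = "anaphase")
  gt <- co$ground_truth
  fates <- gt$true_fate[match(al$cell_ids, gt$cell_id)]
  col2 <- which(abs(al$relative_times - 2) < 1e-9)
  expect_gt(mean(al$values[fates == "high", col2], na.rm = TRUE),
            th$theta_cdk46)
  expect_lt(mean(al$values[fates == "low", col2], na.rm = TRUE),
            th$theta_cdk46)
})

test_that("cumulative fractions count right-censored cells in the denominator", {
  rec <- tibble::tibble(cell_id = c("a", "b", "c"),
                        t_cdk46_on = c(5, 8, NA))
  cc <- cumulative_fraction(rec, "t_cdk46_on", times = c(0, 6, 10))
  expect_equal(cc$fraction, c(0, 1 / 3, 2 / 3))
  expect_true(all(diff(cc$fraction) >= 0))
  expect_true(all(cc$fraction >= 0 & cc$fraction <= 1))
  expect_error(cumulative_fraction(rec, "nope", 1:3),
               class = "cdktrace_parameter_error")
})

test_that("activation curves dominate in the order CDK4/6 > CDK2 > APC/C", {
  co <- simulate_quiescence_release(generator_params(n_cells = 300,
                                                     seed = 42))
  rec <- detect_events(co)
  tt <- seq(0, 24, by = 0.5)
  c46 <- cumulative_fraction(rec, "t_cdk46_on", tt)$fraction
  c2 <- cumulative_fraction(rec, "t_cdk2_on", tt)$fraction
  apc <- cumulative_fraction(rec, "t_apc_off", tt)$fraction
  expect_true(all(c46 >= c2 - 1e-12))
  expect_true(all(c2 >= apc - 1e-12))
})

test_that("bootstrap median bands behave on degenerate and graded inputs", {
  m <- matrix(rep(2, 120), nrow = 12)
  al <- structure(list(relative_times = seq_len(10), values = m,
                       cell_ids = as.character(1:12),
                       anchor_kind = "mitogen_release",
                       channel = "cdk2", n_dropped = 0),
                  class = "aligned_matrix")
  out <- median_with_ci(al, n_boot = 100, seed = 1)
  expect_true(all(out$median == 2))
  expect_true(all(out$hi - out$lo == 0))
  m2 <- matrix(rep(1:11, 10), nrow = 11)
  al$values <- m2; al$cell_ids <- as.character(1:11)
  al$relative_times <- seq_len(10)
  out2 <- median_with_ci(al, n_boot = 100, seed = 1)
  expect_true(all(out2$median == 6))
  expect_error(median_with_ci(structure(list(values = m[1:5, ]),
                                        class = "aligned_matrix")),
               class = "cdktrace_insufficient_data_error")
})

test_that("bootstrap intervals are stable in the number of resamples", {
  co <- simulate_quiescence_release(generator_params(n_cells = 60,
                                                     p_activate = 1,
                                                     seed = 43))
  al <- align_to_event(co, anchor_kind = "mitogen_release", channel = "cdk2")
  a <- median_with_ci(al, n_boot = 1000, seed = 7)
  b <- median_with_ci(al, n_boot = 2000, seed = 7)
  rel <- abs(b$lo - a$lo) / pmax(abs(a$lo), 1e-6)
  expect_lt(stats::median(rel, na.rm = TRUE), 0.05)
})

test_that("stress exit fractions hit the limit cases", {
  p <- generator_params(n_cells = 250, p_activate = 1, noise_sd = 0,
                        seed = 44)
  co <- simulate_quiescence_release(p)
  # everyone exits when the midpoint sits far above the observed range
  all_exit <- apply_perturbation(co, perturbation_spec(
    "stress", t_add = 11, exit_logistic = c(midpoint = 5, steepness = 50)))
  bins <- stress_exit_by_cdk2_bin(all_exit)
  expect_true(all(bins$fraction_low[bins$n > 0] == 1))
  # step limit: bins on either side of the midpoint are pure
  step <- apply_perturbation(co, perturbation_spec(
    "stress", t_add = 11, exit_logistic = c(midpoint = 0.9,
                                            steepness = 1e6)))
  bstep <- stress_exit_by_cdk2_bin(step, bin_edges = c(0.76, 0.9, 1.0))
  expect_equal(bstep$fraction_low[bstep$bin_lo == 0.76 & bstep$n > 0], 1)
  hi_bin <- bstep$fraction_low[bstep$bin_lo == 0.9 & bstep$n > 0]
  if (length(hi_bin) > 0) expect_equal(hi_bin, 0)
  # invariant to cell order and to split-and-pool counting
  sh <- all_exit
  sh$traces <- sh$traces[sample.int(nrow(sh$traces)), ]
  sh$traces <- dplyr::arrange(sh$traces, cell_id, time_h)
  expect_equal(stress_exit_by_cdk2_bin(sh), bins)
  expect_error(stress_exit_by_cdk2_bin(co),
               class = "cdktrace_protocol_error")
})

test_that("unperturbed high-fate trajectories keep CDK4/6 at plateau while CDK2 climbs", {
  co <- simulate_quiescence_release(generator_params(n_cells = 80,
                                                     p_activate = 1,
                                                     seed = 45))
  gt <- co$ground_truth
  ids <- gt$cell_id[gt$true_t_cdk46_on < 10]
  traj <- phase_trajectory(co, ids, t_start = 12, t_end = 20)
  th <- default_thresholds()
  expect_true(all(traj$cdk46_med > th$theta_cdk46))
  expect_gt(stats::cor(traj$time_h, traj$cdk2_med), 0.99)
  expect_error(phase_trajectory(co, ids[1:3]),
               class = "cdktrace_insufficient_data_error")
})

test_that("Rb phospho fractions split cleanly by live CDK4/6 class", {
  co <- simulate_cycling(generator_params(n_cells = 800, duration = 15,
                                          seed = 46))
  thr <- bimodal_threshold(co$ground_truth$rb_phospho)
  tbl <- fraction_rb_phospho_by_class(co, thr, seq(0, 14, by = 2))
  hi <- tbl[tbl$class == "high" & tbl$n >= 10, ]
  lo <- tbl[tbl$class == "low" & tbl$n >= 10, ]
  expect_true(all(hi$fraction_phospho >= 0.95))
  expect_true(all(lo$fraction_phospho <= 0.05))
  co$ground_truth$rb_phospho <- NA_real_
  expect_error(fraction_rb_phospho_by_class(co, thr, seq(0, 14, 2)),
               class = "cdktrace_protocol_error")
})
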