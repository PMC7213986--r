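th <- default_thresholds()

test_that("release fates: persistent activation is high, flat baseline is low", {
  times <- seq(0, 24, by = 0.2)
  raw_high <- ifelse(times >= 8, 0.9, 0.2) + 0.35 * 0.5
  co <- make_cohort(
    make_trace_tbl("up", times, cdk46_raw = raw_high),
    make_trace_tbl("flat", times, cdk46_raw = rep(0.2 + 0.35 * 0.5,
                                                  length(times))))
  f <- classify_cohort(co, context = "quiescence_release")
  expect_equal(f$label[f$cell_id == "up"], "high")
  expect_equal(f$label[f$cell_id == "flat"], "low")
  # determinism: identical input gives identical labels
  expect_identical(f, classify_cohort(co, context = "quiescence_release"))
})

test_that("release classification recovers the generator fraction", {
  co <- simulate_quiescence_release(
    generator_params(n_cells = 1000, seed = 21))
  f <- classify_cohort(co, context = "quiescence_release")
  gt <- co$ground_truth
  truth <- gt$true_fate[match(f$cell_id, gt$cell_id)]
  expect_gte(mean(f$label == truth), 0.95)
  expect_lt(abs(mean(f$label == "high") - mean(gt$true_fate == "high")),
            0.04)
})

test_that("post-mitotic fates follow the 2 h / 10 h threshold rules", {
  times <- seq(0, 24, by = 0.2)
  base <- 0.35 * 0.5
  mk <- function(id, corr) make_trace_tbl(id, times,
                                          cdk46_raw = corr + base,
                                          anaphase_at = 2)
  co <- make_cohort(
    mk("high", rep(0.9, length(times))),
    mk("low", rep(0.2, length(times))),
    mk("delay", ifelse(times >= 8, 0.9, 0.2)),  # rise at anaphase + 6 h
    protocol = "cycling")
  f <- classify_cohort(co, context = "mitotic_exit")
  expect_equal(f$label[f$cell_id == "high"], "high")
  expect_equal(f$label[f$cell_id == "low"], "low")
  expect_equal(f$label[f$cell_id == "delay"], "delay")
  expect_equal(f$t_delay[f$cell_id == "delay"], 6, tolerance = 0.21)
  # the three labels partition the cohort
  expect_true(all(f$label %in% c("high", "low", "delay")))
  # a cell without anaphase is a protocol error
  co2 <- make_cohort(make_trace_tbl("x", times), protocol = "cycling")
  expect_error(classify_cohort(co2, context = "mitotic_exit"),
               class = "cdktrace_protocol_error")
})

test_that("post-mitotic classification recovers generator fates", {
  co <- simulate_cycling(generator_params(n_cells = 400, seed = 22))
  f <- classify_cohort(co, context = "mitotic_exit")
  gt <- co$ground_truth
  truth <- gt$true_fate[match(f$cell_id, gt$cell_id)]
  expect_gte(mean(f$label == truth), 0.95)
  # noise-free cohorts classify perfectly
  co0 <- simulate_cycling(generator_params(n_cells = 150, noise_sd = 0,
                                           seed = 23))
  f0 <- classify_cohort(co0, context = "mitotic_exit")
  gt0 <- co0$ground_truth
  expect_equal(mean(f0$label == gt0$true_fate[match(f0$cell_id,
                                                    gt0$cell_id)]), 1)
})

test_that("stress outcomes score CDK2 at 15 h against threshold and decline", {
  times <- seq(0, 20, by = 0.2)
  base46 <- ifelse(times >= 6, 0.9, 0.2)
  mk <- function(id, cdk2) make_trace_tbl(
    id, times, cdk46_raw = base46 + 0.35 * cdk2, cdk2 = cdk2)
  falling <- ifelse(times <= 11, 0.5 + 0.035 * times,
                    pmax(0.885 - 0.12 * (times - 11), 0.5))
  rising <- 0.5 + 0.035 * times
  plateau_rev <- ifelse(times <= 11, 0.5 + 0.05 * times,
                        pmax(1.05 - 0.06 * (times - 11), 0.79))
  co <- make_cohort(mk("fall", falling), mk("rise", rising),
                    mk("plateau_rev", plateau_rev))
  co$perturbation <- perturbation_spec("stress", t_add = 11)
  f <- classify_cohort(co, context = "stress_outcome")
  expect_equal(f$label[f$cell_id == "fall"], "low")      # below 0.76 at 15 h
  expect_equal(f$label[f$cell_id == "rise"], "inc")
  # still above 0.76 at 15 h but declined > 20% from its value at stress
  expect_equal(f$label[f$cell_id == "plateau_rev"], "low")
})

test_that("stress outcome labels recover the generator's response", {
  co <- simulate_quiescence_release(generator_params(n_cells = 1200,
                                                     seed = 24))
  st <- apply_perturbation(co, perturbation_spec("stress", t_add = 11))
  f <- classify_cohort(st, context = "stress_outcome")
  gt <- st$ground_truth
  j <- dplyr::left_join(f, gt, by = "cell_id")
  j <- j[j$eligible %in% TRUE, ]
  expect_gt(nrow(j), 30)
  expect_gte(mean((j$label == "low") == j$responded_to_stress), 0.95)
})

test_that("bimodal thresholding recovers a constructed mixture boundary", {
  set.seed(31)
  v <- exp(c(rnorm(1000, log(1), 0.3), rnorm(1000, log(10), 0.3)))
  thr <- bimodal_threshold(v)
  mid <- exp((log(1) + log(10)) / 2)  # 3.162
  expect_lt(abs(log(thr) - log(mid)), 0.1 * log(10))
  # symmetric two-point mass splits at the geometric mean
  v2 <- rep(c(1, 10), each = 100) * exp(rnorm(200, 0, 0.01))
  expect_lt(abs(bimodal_threshold(v2) - 3.162), 0.35)
  expect_warning(t3 <- bimodal_threshold(rep(5, 100)), "degenerate")
  expect_equal(t3, 5)
  expect_error(bimodal_threshold(1:10),
               class = "cdktrace_insufficient_data_error")
})

test_that("the bimodality decision separates dipped from merged mixtures", {
  set.seed(32)
  expect_true(is_bimodal(c(rnorm(800, 0.2, 0.05), rnorm(800, 0.9, 0.05))))
  expect_false(is_bimodal(rnorm(1500, 0.5, 0.1)))
})
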