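test_that("activating cells order their true events CDK4/6-on < CDK2-on < APC/C-off", {
  co <- simulate_quiescence_release(
    generator_params(n_cells = 50, p_activate = 1, noise_sd = 0, seed = 4))
  gt <- co$ground_truth
  ok <- !gt$truncated
  expect_true(any(ok))
  expect_true(all(gt$true_t_cdk46_on[ok] < gt$true_t_cdk2_on[ok]))
  expect_true(all(gt$true_t_cdk2_on[ok] < gt$true_t_apc_off[ok]))
})

test_that("a null cohort stays flat at baseline with no degron rise", {
  co <- simulate_quiescence_release(
    generator_params(n_cells = 20, p_activate = 0, noise_sd = 0, seed = 4))
  p <- co$params
  corr <- co$traces$cdk46_raw - p$f_true * co$traces$cdk2
  expect_true(all(abs(corr - p$baseline_cdk46) < 1e-9))
  # degron never rises above its constant background
  expect_true(all(co$traces$apc_degron == p$degron_background))
  expect_true(all(co$ground_truth$true_fate == "low"))
})

test_that("the activating fraction respects p_activate within its binomial band", {
  co <- simulate_quiescence_release(
    generator_params(n_cells = 2000, p_activate = 0.54, seed = 6))
  frac <- mean(co$ground_truth$true_fate == "high")
  band <- 1.96 * sqrt(0.54 * 0.46 / 2000)
  expect_lt(abs(frac - 0.54), band)
})

test_that("fixed seeds reproduce cohorts bit-identically; new seeds change draws", {
  p <- generator_params(n_cells = 15, seed = 8)
  a <- simulate_quiescence_release(p)
  b <- simulate_quiescence_release(p)
  expect_identical(a$traces, b$traces)
  expect_identical(a$ground_truth, b$ground_truth)
  c <- simulate_quiescence_release(generator_params(n_cells = 15, seed = 9))
  expect_false(identical(a$traces, c$traces))
})

test_that("generated activities are nonnegative and the latent degron is nondecreasing", {
  co <- simulate_quiescence_release(
    generator_params(n_cells = 40, noise_sd = 0.1, seed = 10))
  expect_true(all(co$traces$cdk46_raw >= 0))
  expect_true(all(co$traces$cdk2 >= 0))
  expect_true(all(co$traces$apc_degron >= 0))
  diffs <- co$latent |>
    dplyr::group_by(cell_id) |>
    dplyr::summarise(mono = all(diff(apc_true) >= -1e-12))
  expect_true(all(diffs$mono))
})

test_that("a too-short recording warns and flags truncated cells", {
  expect_warning(
    co <- simulate_quiescence_release(
      generator_params(n_cells = 60, p_activate = 1, duration = 10,
                       seed = 2)),
    "truncated")
  expect_true(any(co$ground_truth$truncated))
})

test_that("forced mitotic fates pin the post-anaphase signals", {
  th <- default_thresholds()
  hi <- simulate_cycling(generator_params(
    n_cells = 20, mitotic_fate_probs = c(high = 1, low = 0, delay = 0),
    noise_sd = 0, seed = 3))
  at2 <- hi$latent |>
    dplyr::left_join(dplyr::select(hi$ground_truth, cell_id, anaphase_time),
                     by = "cell_id") |>
    dplyr::group_by(cell_id) |>
    dplyr::summarise(v = cdk46_true[which.min(abs(time_h -
                                                    (anaphase_time[1] + 2)))])
  expect_true(all(at2$v > th$theta_cdk46))

  lo <- simulate_cycling(generator_params(
    n_cells = 20, mitotic_fate_probs = c(high = 0, low = 1, delay = 0),
    noise_sd = 0, seed = 3))
  post <- lo$latent |>
    dplyr::left_join(dplyr::select(lo$ground_truth, cell_id, anaphase_time),
                     by = "cell_id") |>
    dplyr::filter(time_h > anaphase_time)
  expect_true(all(post$apc_true == 0))
})

test_that("every cycling cell carries exactly one anaphase annotation in span", {
  co <- simulate_cycling(generator_params(n_cells = 30, seed = 5))
  per <- co$traces |>
    dplyr::group_by(cell_id) |>
    dplyr::summarise(n_ana = sum(is_anaphase))
  expect_true(all(per$n_ana == 1))
})

test_that("a step exit rule makes stress outcomes deterministic in CDK2", {
  co <- simulate_quiescence_release(
    generator_params(n_cells = 400, p_activate = 1, noise_sd = 0, seed = 7))
  spec <- perturbation_spec("stress", t_add = 11,
                            exit_logistic = c(midpoint = 0.9,
                                              steepness = 1e6))
  st <- apply_perturbation(co, spec)
  gt <- st$ground_truth
  cdk2_at <- st$latent |>
    dplyr::group_by(cell_id) |>
    dplyr::summarise(v = stats::approx(time_h, cdk2_true, 11, rule = 2)$y)
  # responders' CDK2 froze at its pre-stress value, so v at 11 h is exact
  g1 <- is.na(gt$true_t_apc_off) | gt$true_t_apc_off > 11
  below <- g1 & cdk2_at$v < 0.899
  above <- g1 & cdk2_at$v > 0.901
  expect_true(all(gt$responded_to_stress[below]))
  expect_true(!any(gt$responded_to_stress[above]))
})

test_that("full CDK4/6 inhibition leaves exactly the CDK2 cross-contribution", {
  p <- generator_params(n_cells = 25, p_activate = 1, noise_sd = 0, seed = 1)
  co <- simulate_quiescence_release(p)
  inh <- apply_perturbation(co, perturbation_spec("cdk46_inhibitor",
                                                  t_add = 20,
                                                  residual_fraction = 0))
  post <- dplyr::filter(inh$traces, time_h >= 20 + 2 * p$dt)
  post_lat <- dplyr::filter(inh$latent, time_h >= 20 + 2 * p$dt)
  sg2 <- inh$ground_truth$cell_id[!is.na(inh$ground_truth$true_t_apc_off) &
                                    inh$ground_truth$true_t_apc_off < 20]
  keep <- post$cell_id %in% sg2
  expect_equal(post$cdk46_raw[keep],
               p$f_true * post_lat$cdk2_true[keep], tolerance = 1e-9)
})

test_that("a CDK2 inhibitor drops the raw CDK4/6 reporter by the set fraction", {
  p <- generator_params(n_cells = 40, p_activate = 1, noise_sd = 0, seed = 2)
  co <- simulate_quiescence_release(p)
  inh <- apply_perturbation(co, perturbation_spec("cdk2_inhibitor",
                                                  t_add = 11,
                                                  cdk2_reduction = 0.15))
  # compare raw just before the add with raw once the decay has settled
  pre <- dplyr::filter(inh$traces, abs(time_h - 11) < 1e-9)
  post <- dplyr::filter(inh$traces, abs(time_h - 13) < 1e-9)
  gt <- inh$ground_truth
  active <- gt$cell_id[!is.na(gt$true_t_cdk46_on) & gt$true_t_cdk46_on < 10]
  drop <- 1 - post$cdk46_raw[match(active, post$cell_id)] /
    pre$cdk46_raw[match(active, pre$cell_id)]
  expect_true(all(abs(drop - 0.15) < 0.02))
})

test_that("ground-truth stress response is nonincreasing across CDK2 bins", {
  co <- simulate_quiescence_release(
    generator_params(n_cells = 3000, seed = 11))
  st <- apply_perturbation(co, perturbation_spec("stress", t_add = 11))
  gt <- st$ground_truth
  v <- st$latent |>
    dplyr::group_by(cell_id) |>
    dplyr::summarise(v = stats::approx(time_h, cdk2_true, 11, rule = 2)$y)
  g1 <- is.na(gt$true_t_apc_off) | gt$true_t_apc_off > 11
  df <- data.frame(v = v$v[g1], exit = gt$responded_to_stress[g1])
  df$bin <- cut(df$v, c(0.4, 0.6, 0.8, 1.0))
  frac <- tapply(df$exit, df$bin, mean)
  expect_true(all(diff(frac[!is.na(frac)]) <= 0))
  # unknown kinds are rejected
  expect_error(perturbation_spec("heat_shock"),
               class = "cdktrace_parameter_error")
})

test_that("generator parameter validation names the offending field", {
  expect_error(generator_params(p_activate = 2), "p_activate")
  expect_error(generator_params(mitotic_fate_probs = c(0.5, 0.4, 0.2)),
               "mitotic_fate_probs")
  expect_error(generator_params(rise_time_cdk46 = 6), "rise_time")
})
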