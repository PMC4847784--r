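test_that("wald_test reproduces the worked-example confidence intervals", {
  em <- wald_test(log(0.7026), 0.1439, alpha = 0.05)
  expect_equal(round(em$ci_hr, 4), c(0.5299, 0.9315))
  expect_true(em$reject)
  nv <- wald_test(log(0.8318), 0.1152, alpha = 0.05)
  expect_equal(round(nv$ci_hr, 4), c(0.6637, 1.0425))
  expect_false(nv$reject)
  z0 <- wald_test(0, 0.2)
  expect_equal(z0$z_stat, 0)
  expect_false(z0$reject)
  expect_equal(z0$ci_hr[1] * z0$ci_hr[2], 1, tolerance = 1e-12)
  expect_error(wald_test(0.1, 0), "positive")
  expect_error(wald_test(0.1, 0.1, alpha = 1.2), "alpha")
})

test_that("rejection and the hazard-ratio interval excluding 1 are dual", {
  set.seed(5)
  for (i in 1:50) {
    est <- stats::rnorm(1, 0, 0.5)
    se <- stats::runif(1, 0.05, 0.5)
    a <- stats::runif(1, 0.01, 0.2)
    w <- wald_test(est, se, a)
    excludes <- w$ci_hr[1] > 1 || w$ci_hr[2] < 1
    expect_identical(w$reject, excludes)
  }
})

test_that("intervals are nested in the confidence level", {
  w95 <- wald_test(-0.3, 0.12, 0.05)
  w90 <- wald_test(-0.3, 0.12, 0.10)
  expect_gt(w90$ci_log[1], w95$ci_log[1])
  expect_lt(w90$ci_log[2], w95$ci_log[2])
  i95 <- interaction_ci(-0.35, 0.26, 0.02, 0.09, 0.05)
  i90 <- interaction_ci(-0.35, 0.26, 0.02, 0.09, 0.10)
  expect_gt(i90$lower, i95$lower)
  expect_lt(i90$upper, i95$upper)
})

test_that("interaction_ci reproduces the worked example", {
  # the published endpoints come from unrounded inputs; reproducing them
  # from the printed 4-digit estimates carries their rounding error
  ci90 <- interaction_ci(log(0.7026), 0.259, 0.1439^2, 0.3049^2, alpha = 0.10)
  expect_lt(max(abs(c(ci90$lower, ci90$upper) - c(-1.1667, -0.0574))), 5e-4)
  expect_true(ci90$significant)
  ci95 <- interaction_ci(log(0.7026), 0.259, 0.1439^2, 0.3049^2, alpha = 0.05)
  expect_equal(round(ci95$lower, 4), -1.2728)
  # the matching upper endpoint from the same arithmetic
  expect_equal(round(ci95$upper, 4), 0.0488)
  expect_false(ci95$significant)
  ci0 <- interaction_ci(-0.2, -0.2, 0.01, 0.01, 0.05)
  expect_equal(ci0$estimate, 0)
  expect_false(ci0$significant)
  expect_error(interaction_ci(0, 0, 0, 0), "degenerate")
})

test_that("the parametric bootstrap is reproducible and reports Eq-8 variances", {
  sp <- trial_scenario(n_per_arm = 120, ppv = 0.7, hr_pos = 0.6,
                       censor_rate = 0.2, seed = 17)
  d <- simulate_trial(sp)
  ef <- em_fit(d, 0.7, log(0.6))
  b1 <- parametric_bootstrap(ef, B = 30, seed = 99)
  b2 <- parametric_bootstrap(ef, B = 30, seed = 99)
  expect_identical(b1$draws_pos, b2$draws_pos)
  b3 <- parametric_bootstrap(ef, B = 30, seed = 100)
  expect_false(identical(b1$draws_pos, b3$draws_pos))
  expect_equal(b1$var_pos, stats::var(b1$draws_pos), tolerance = 1e-12)
  expect_equal(b1$se_pos, sqrt(b1$var_pos), tolerance = 1e-12)
  expect_error(parametric_bootstrap(ef, B = 1), "at least 2")
  # refits that cannot converge must invalidate the analysis, not degrade it
  expect_error(
    suppressWarnings(parametric_bootstrap(ef, B = 10, seed = 1, max_iter = 1L)),
    "unreliable")
})

test_that("bootstrap intervals come in normal (primary) and percentile flavors", {
  sp <- trial_scenario(n_per_arm = 120, ppv = 0.7, hr_pos = 0.6,
                       censor_rate = 0.2, seed = 18)
  d <- simulate_trial(sp)
  ef <- em_fit(d, 0.7, log(0.6))
  bt <- parametric_bootstrap(ef, B = 40, seed = 5)
  ci_n <- confint(bt, parm = "pos", level = 0.95)
  w <- wald_test(ef$params$log_hr_pos, bt$se_pos, 0.05)
  expect_equal(unname(ci_n[1, ]), w$ci_log, tolerance = 1e-12)
  ci_p <- confint(bt, parm = "pos", type = "percentile")
  expect_gte(ci_p[1, "lower"], min(bt$draws_pos))
  expect_lte(ci_p[1, "upper"], max(bt$draws_pos))
})

test_that("bootstrap SE tracks the Monte-Carlo sampling SD", {
  sp <- trial_scenario(n_per_arm = 300, ppv = 0.75, hr_pos = 0.7,
                       censor_rate = 0.3, seed = 23)
  d <- simulate_trial(sp)
  ef <- em_fit(d, 0.75, log(0.7))
  bt <- parametric_bootstrap(ef, B = 200, seed = 7)
  draws <- numeric(150)
  for (r in 1:150) {
    spr <- sp
    spr$seed <- 5000L + r
    er <- suppressWarnings(em_fit(simulate_trial(spr), 0.75, log(0.7)))
    draws[r] <- er$params$log_hr_pos
  }
  ratio <- bt$se_pos / stats::sd(draws)
  expect_gt(ratio, 0.7)
  expect_lt(ratio, 1.43)
})

test_that("simulated bootstrap trials respect the fitted design", {
  sp <- trial_scenario(n_per_arm = 80, ppv = 0.7, hr_pos = 0.6,
                       censor_rate = 0.3, seed = 31)
  d <- simulate_trial(sp)
  ef <- em_fit(d, 0.7, log(0.6))
  sims <- simulate(ef, nsim = 5, seed = 1)
  expect_length(sims, 5)
  for (s in sims) {
    expect_s3_class(s, "trial_data")
    expect_identical(s$treatment, d$treatment)   # covariates kept as observed
    expect_lte(max(s$time), max(d$time))          # support-censoring rule
    expect_true(all(s$true_class %in% 0:1))
  }
  # class frequencies follow gamma-hat
  xb <- vapply(simulate(ef, nsim = 40, seed = 2),
               function(s) mean(s$true_class), numeric(1))
  expect_lt(abs(mean(xb) - ef$params$gamma), 0.05)
})

test_that("analyze_trial assembles a complete serialized report", {
  sp <- trial_scenario(n_per_arm = 100, ppv = 0.75, hr_pos = 0.7,
                       hr_neg = 1.2, censor_rate = 0.3, seed = 41)
  d <- simulate_trial(sp)
  an <- analyze_trial(d, ppv = 0.75, B = 50, alpha = 0.05, seed = 3,
                      protocol_hr = 0.7)
  expect_s3_class(an, "enrichment_analysis")
  f <- withr::local_tempfile(fileext = ".json")
  rep <- write_analysis_report(an, f)
  parsed <- jsonlite::read_json(f)
  expect_equal(parsed$em_hr_pos, exp(an$em$params$log_hr_pos),
               tolerance = 1e-8)
  expect_equal(parsed$bootstrap_B, 50L)
  expect_true(is.logical(parsed$interaction_significant))
})
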