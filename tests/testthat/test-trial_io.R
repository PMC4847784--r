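test_that("read_trial parses a plain CSV and preserves row order", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,event,treatment", "1.0,1,1", "2.0,0,0", "3.0,1,1"), f)
  d <- read_trial(f)
  expect_s3_class(d, "trial_data")
  expect_equal(nrow(d), 3L)
  expect_equal(d$time, c(1, 2, 3))
  expect_equal(d$event, c(1L, 0L, 1L))
  expect_equal(d$treatment, c(1L, 0L, 1L))
})

test_that("validation errors name the offending row", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,event,treatment", "1.0,1,1", "2.0,2,0", "3.0,1,1"), f)
  expect_error(read_trial(f), "row 2")
  expect_error(trial_data(c(1, -2, 3), c(1, 1, 1), c(0, 1, 0)), "row 2")
  expect_error(trial_data(c(1, 2), c(1, 1), c(0, 3)), "row 2")
  expect_error(trial_data(1, 1, 1), "at least 2")
})

test_that("schema mapping and covariate columns work, order preserved", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,status,arm,age,sex", "1.5,1,1,60,1", "2.5,0,0,55,0"), f)
  d <- read_trial(f, schema = c(time = "t", event = "status",
                                treatment = "arm"))
  expect_equal(attr(d, "covariates"), c("age", "sex"))
  expect_equal(d$age, c(60, 55))
  expect_error(read_trial(f, schema = c(bogus = "t")), "unknown schema")
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("event,treatment", "1,1"), f2)
  expect_error(read_trial(f2), "'time'")
})

test_that("write_trial round-trips exactly, with and without extras", {
  for (cfg in list(list(cov = FALSE, tc = FALSE), list(cov = TRUE, tc = FALSE),
                   list(cov = TRUE, tc = TRUE))) {
    set.seed(42)
    n <- 20
    d <- trial_data(
      time = stats::rexp(n) + 1e-9, event = stats::rbinom(n, 1, 0.7),
      treatment = rep(0:1, each = n / 2),
      covariates = if (cfg$cov)
        data.frame(a = stats::rnorm(n), b = stats::runif(n),
                   c = stats::rnorm(n)) else NULL,
      true_class = if (cfg$tc) stats::rbinom(n, 1, 0.5) else NULL)
    f <- withr::local_tempfile(fileext = ".csv")
    write_trial(d, f)
    d2 <- read_trial(f)
    expect_identical(d2$time, d$time)
    expect_identical(d2$event, d$event)
    expect_identical(d2$treatment, d$treatment)
    expect_identical(attr(d2, "covariates"), attr(d, "covariates"))
    for (nm in attr(d, "covariates")) expect_identical(d2[[nm]], d[[nm]])
    if (cfg$tc) expect_identical(d2$true_class, d$true_class)
    else expect_null(d2$true_class)
  }
  expect_error(suppressWarnings(
    write_trial(random_trial(10, seed = 1), "/nonexistent/x/y.csv")),
    "cannot write")
})

test_that("scenario YAML files are read back into valid scenarios", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_per_arm: 50", "ppv: 0.7", "hr_pos: 0.8", "censor_rate: 0.2",
               "seed: 9"), f)
  sp <- read_scenario(f)
  expect_s3_class(sp, "trial_scenario")
  expect_equal(sp$n_per_arm, 50L)
  expect_equal(sp$hr_neg, 1)
  f2 <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_per_arm: 50", "ppv: 0.7", "hr_pos: 0.8", "bogus: 1"), f2)
  expect_error(read_scenario(f2), "unknown scenario fields")
})

test_that("simulate_trial honours degenerate settings and is reproducible", {
  sp1 <- trial_scenario(n_per_arm = 40, ppv = 1, hr_pos = 0.7, seed = 3)
  d1 <- simulate_trial(sp1)
  expect_true(all(d1$true_class == 1L))
  sp0 <- trial_scenario(n_per_arm = 40, ppv = 0.6, hr_pos = 0.7,
                        censor_rate = 0, seed = 3)
  d0 <- simulate_trial(sp0)
  expect_true(all(d0$event == 1L))
  expect_identical(simulate_trial(sp0), simulate_trial(sp0))
  sp2 <- sp0
  sp2$seed <- 4L
  expect_false(identical(simulate_trial(sp0)$time, simulate_trial(sp2)$time))
  expect_equal(sum(d0$treatment), 40L)  # exact 1:1 randomization
})

test_that("censoring calibration hits the target rate", {
  # Monte-Carlo check at the reference design
  cens <- pos <- numeric(200)
  for (r in 1:200) {
    sp <- trial_scenario(n_per_arm = 300, ppv = 0.5, hr_pos = 0.85,
                         hr_neg = 1, censor_rate = 0.3, seed = 100 + r)
    d <- simulate_trial(sp)
    cens[r] <- mean(1 - d$event)
    pos[r] <- mean(d$true_class)
  }
  expect_lt(abs(mean(cens) - 0.3), 0.02)
  expect_lt(abs(mean(pos) - 0.5), 0.01)
  # large-n convergence, exponential and Weibull event times
  spL <- trial_scenario(n_per_arm = 50000, ppv = 0.6, hr_pos = 0.8,
                        censor_rate = 0.2, seed = 5)
  expect_lt(abs(mean(1 - simulate_trial(spL)$event) - 0.2), 0.005)
  spW <- trial_scenario(n_per_arm = 50000, ppv = 0.5, hr_pos = 0.75,
                        censor_rate = 0.3, shape_pos = 2, seed = 6)
  expect_lt(abs(mean(1 - simulate_trial(spW)$event) - 0.3), 0.005)
})

test_that("null hazard ratio gives exchangeable arms", {
  rej <- 0
  for (r in 1:40) {
    sp <- trial_scenario(n_per_arm = 200, ppv = 0.5, hr_pos = 1, hr_neg = 1,
                         censor_rate = 0.2, seed = 700 + r)
    d <- simulate_trial(sp)
    p <- 1 - stats::pchisq(
      survival::survdiff(survival::Surv(time, event) ~ treatment, d)$chisq, 1)
    rej <- rej + (p < 0.05)
  }
  expect_lte(rej, 7)  # binomial(40, 0.05): P(X > 7) < 1e-3
})
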