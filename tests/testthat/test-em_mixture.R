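make_toy_params <- function(gamma = 0.6) {
  bp <- breslow_baseline(trial_data(c(1, 2, 4), c(1L, 1L, 1L), c(0L, 1L, 0L)),
                         rep(1, 3), 0)
  bn <- breslow_baseline(trial_data(c(1.5, 3), c(1L, 1L), c(0L, 1L)),
                         rep(1, 2), 0)
  mixture_params(gamma, log_hr_pos = log(0.7), log_hr_neg = 0.2,
                 baseline_pos = bp, baseline_neg = bn)
}

test_that("class_evidence matches a hand-evaluated posterior", {
  p <- make_toy_params(0.6)
  d <- trial_data(time = c(1.2, 3, 4.5), event = c(1L, 0L, 1L),
                  treatment = c(1L, 0L, 1L))
  post <- class_evidence(d, p)
  # direct evaluation of the class evidence, written out longhand
  stepval <- function(ts, vs, t) if (any(ts <= t)) vs[max(which(ts <= t))] else 0
  expect_A <- expect_B <- numeric(3)
  for (i in 1:3) {
    ep <- log(0.7) * d$treatment[i]
    en <- 0.2 * d$treatment[i]
    hp <- stepval(p$baseline_pos$times, p$baseline_pos$jumps, d$time[i])
    Hp <- stepval(p$baseline_pos$times, p$baseline_pos$cumulative, d$time[i])
    hn <- stepval(p$baseline_neg$times, p$baseline_neg$jumps, d$time[i])
    Hn <- stepval(p$baseline_neg$times, p$baseline_neg$cumulative, d$time[i])
    expect_A[i] <- 0.6 * (hp * exp(ep))^d$event[i] * exp(-Hp * exp(ep))
    expect_B[i] <- 0.4 * (hn * exp(en))^d$event[i] * exp(-Hn * exp(en))
  }
  expect_equal(post$evidence_pos, expect_A, tolerance = 1e-12)
  expect_equal(post$evidence_neg, expect_B, tolerance = 1e-12)
  expect_equal(post$x_hat, expect_A / (expect_A + expect_B), tolerance = 1e-12)
  expect_true(all(post$x_hat >= 0 & post$x_hat <= 1))
  # and the observed log-likelihood is the matching sum
  expect_equal(observed_loglik(d, p), sum(log(expect_A + expect_B)),
               tolerance = 1e-12)
  expect_equal(complete_data_loglik(d, p, c(1, 1, 1)), sum(log(expect_A)),
               tolerance = 1e-12)
})

test_that("identical class models collapse the posterior to the prior", {
  d <- random_trial(30, seed = 4)
  bh <- breslow_baseline(d, rep(1, 30), 0)
  p <- mixture_params(0.37, log_hr_pos = -0.2, log_hr_neg = -0.2,
                      baseline_pos = bh, baseline_neg = bh)
  post <- class_evidence(d, p)
  expect_equal(post$x_hat, rep(0.37, 30), tolerance = 1e-12)
})

test_that("records outside both baselines' support fall back to the prior", {
  p <- make_toy_params(0.6)
  d <- trial_data(time = c(0.5, 2), event = c(1L, 1L), treatment = c(0L, 0L))
  expect_warning(post <- class_evidence(d, p), "zero evidence")
  expect_equal(post$x_hat[1], 0.6)
  expect_warning(observed_loglik(d, p), "floored")
})

test_that("update_gamma is the clipped posterior mean", {
  mk <- function(x) structure(list(x_hat = x, evidence_pos = x,
                                   evidence_neg = 1 - x),
                              class = "posterior_membership")
  expect_equal(update_gamma(mk(c(0.2, 0.8))), 0.5)
  expect_equal(update_gamma(mk(c(0.3, 0.5, 0.7, 0.9))), 0.6)
  expect_equal(update_gamma(mk(c(1, 1, 1, 1))), 1 - 1e-6)
})

test_that("a near-1 fixed PPV reduces the EM to the naive fit", {
  d <- random_trial(120, seed = 6)
  nf <- fit_naive_cox(d)
  ef <- em_fit(d, ppv_init = 1 - 1e-6, log_hr_init_pos = 0,
               fix_gamma = TRUE)
  expect_equal(ef$params$log_hr_pos, nf$log_hr, tolerance = 1e-4)
})

test_that("EM log-likelihood ascends across random datasets", {
  # the lambda+/shared-baseline update is a hybrid (ECM-style) step, so a
  # small transient slack is allowed; net ascent must always hold
  worst <- 0
  for (s in 1:100) {
    d <- random_trial(50, seed = 100 + s, censor = 0.2)
    ef <- suppressWarnings(em_fit(d, ppv_init = 0.6,
                                  log_hr_init_pos = log(0.8)))
    tr <- ef$loglik_trace
    if (length(tr) > 1) {
      worst <- max(worst, -min(diff(tr)))
      expect_gt(tr[length(tr)], tr[1] - 1e-8)
    }
  }
  expect_lt(worst, 0.1)
})

test_that("a converged fit is stable under one more module-level sweep", {
  d <- random_trial(200, seed = 12, censor = 0.2)
  ef <- em_fit(d, ppv_init = 0.7, log_hr_init_pos = log(0.8))
  expect_true(ef$converged)
  post <- class_evidence(d, ef$params)
  g2 <- update_gamma(post)
  f2 <- fit_weighted_cox(d, post$x_hat, init = ef$params$log_hr_pos)
  expect_lt(abs(g2 - ef$params$gamma), 5e-3)
  expect_lt(abs(f2$log_hr - ef$params$log_hr_pos), 5e-2)
})

test_that("the posterior mean equals the fitted mixing proportion exactly", {
  d <- random_trial(100, seed = 8, censor = 0.2)
  ef <- em_fit(d, ppv_init = 0.6, log_hr_init_pos = -0.3)
  expect_equal(mean(ef$posterior$x_hat), ef$params$gamma, tolerance = 1e-12)
  expect_true(all(abs(ef$posterior$x_hat -
                        ef$posterior$evidence_pos /
                        (ef$posterior$evidence_pos +
                           ef$posterior$evidence_neg)) < 1e-8))
})

test_that("posterior memberships track the latent class in informative data", {
  sp <- trial_scenario(n_per_arm = 2000, ppv = 0.6, hr_pos = 0.5, hr_neg = 1,
                       censor_rate = 0.1, seed = 21)
  d <- simulate_trial(sp)
  ef <- em_fit(d, ppv_init = 0.6, log_hr_init_pos = log(0.5))
  xh <- ef$posterior$x_hat
  expect_gt(mean(xh[d$true_class == 1]), mean(xh[d$true_class == 0]))
})

test_that("large samples recover the design parameters", {
  sp <- trial_scenario(n_per_arm = 3000, ppv = 0.7, hr_pos = 0.7,
                       censor_rate = 0.2, seed = 11)
  d <- simulate_trial(sp)
  ef <- em_fit(d, ppv_init = 0.7, log_hr_init_pos = log(0.7))
  expect_lt(abs(exp(ef$params$log_hr_pos) - 0.7), 0.05)
  expect_lt(abs(ef$params$gamma - 0.7), 0.02)
})

test_that("covariates are carried through both classes", {
  d <- random_trial(150, seed = 31, covariate = TRUE)
  ef <- em_fit(d, ppv_init = 0.7, log_hr_init_pos = -0.2, fix_hr_neg = FALSE)
  expect_named(ef$params$coef_pos, "x1")
  expect_named(ef$params$coef_neg, "x1")
  expect_true(is.finite(ef$params$coef_pos[["x1"]]))
  pr <- predict(ef, type = "posterior")
  expect_length(pr, 150)
  sv <- predict(ef, type = "survival")
  expect_true(all(sv >= 0 & sv <= 1))
})

test_that("em_fit flags rather than raises non-convergence", {
  d <- random_trial(80, seed = 13, censor = 0.2)
  ef <- suppressWarnings(em_fit(d, 0.6, log(0.8), tol = 0, tol_rel = 0,
                                max_iter = 3L))
  expect_false(ef$converged)
  expect_equal(ef$n_iter, 3L)
})
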