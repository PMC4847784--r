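# shared fixtures and oracles, built in code at test time

# small random right-censored two-arm trial
random_trial <- function(n = 60, seed = NULL, censor = 0.3, log_hr = -0.3,
                         covariate = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  z <- c(0L, 1L, stats::rbinom(n - 2, 1, 0.5))  # both arms guaranteed
  x1 <- if (covariate) stats::rnorm(n) else NULL
  eta <- log_hr * z + if (covariate) 0.4 * x1 else 0
  tt <- stats::rexp(n) / exp(eta)
  cc <- if (censor > 0) stats::rexp(n, censor) else rep(Inf, n)
  trial_data(time = pmin(tt, cc), event = as.integer(tt <= cc), treatment = z,
             covariates = if (covariate) data.frame(x1 = x1) else NULL)
}

# weighted Breslow partial log-likelihood evaluated directly in R
# (independent of the package's Newton path)
pl_loglik <- function(d, w, lam) {
  vapply(lam, function(l) {
    s <- 0
    for (i in which(d$event == 1L & w > 0)) {
      rs <- d$time >= d$time[i]
      s <- s + w[i] * (l * d$treatment[i] -
                         log(sum(w[rs] * exp(l * d$treatment[rs]))))
    }
    s
  }, numeric(1))
}

ref_coxph <- function(d, weights = NULL) {
  survival::coxph(survival::Surv(d$time, d$event) ~ d$treatment,
                  weights = weights, ties = "breslow")
}

# ---- cached grid study shared by the global-bias and PPV-recovery checks ----
.acc_cache <- new.env(parent = emptyenv())

acceptance_grid <- function() {
  if (!is.null(.acc_cache$grid)) return(.acc_cache$grid)
  cells <- expand.grid(ppv = c(0.5, 0.7, 0.9), hr = c(0.7, 0.85),
                       cr = c(0, 0.3))
  res <- lapply(seq_len(nrow(cells)), function(i) {
    sp <- trial_scenario(n_per_arm = 300, ppv = cells$ppv[i],
                         hr_pos = cells$hr[i], hr_neg = 1,
                         censor_rate = cells$cr[i], seed = 20L + i)
    run_scenario(sp, n_reps = 500, B = 0, seed = 11L)
  })
  .acc_cache$grid <- list(cells = cells, res = res)
  .acc_cache$grid
}
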