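# censoring distribution of the observed data (reverse Kaplan-Meier),
# as a discrete sampling distribution: mass at each censoring time plus the
# residual mass, assigned to the largest observed time
censoring_distribution <- function(data) {
  tmax <- max(data$time)
  if (!any(data$event == 0L))
    return(list(times = numeric(0), probs = numeric(0), tmax = tmax))
  km <- survival::survfit(survival::Surv(data$time, 1 - data$event) ~ 1)
  drop <- which(diff(c(1, km$surv)) < 0)
  times <- km$time[drop]
  probs <- -diff(c(1, km$surv))[drop]
  list(times = times, probs = probs, tmax = tmax)
}

sample_censoring <- function(n, cd) {
  vals <- c(cd$times, cd$tmax)
  probs <- c(cd$probs, max(0, 1 - sum(cd$probs)))
  vals[sample.int(length(vals), n, replace = TRUE, prob = probs)]
}

# inverse-transform draw from a step cumulative hazard scaled by exp(eta);
# draws beyond the support return Inf (the caller censors at the last
# observed time via the censoring draw)
sample_step_ph <- function(bh, eta) {
  u <- stats::rexp(length(eta)) / exp(eta)
  j <- findInterval(u, bh$cumulative, left.open = TRUE) + 1L
  out <- rep(Inf, length(eta))
  ok <- j <= length(bh$times)
  out[ok] <- bh$times[j[ok]]
  out
}

#' Simulate trials from a fitted mixture Cox model
#'
#' Draws parametric-bootstrap replicates of the trial from the fitted
#' probability model: latent class Bernoulli(`gamma_hat`) per patient,
#' event times by inverse transform on the estimated class-specific step
#' cumulative hazard scaled by the patient's own risk score (treatment and
#' covariates kept at their observed values), and censoring times resampled
#' from the reverse Kaplan-Meier censoring distribution of the original
#' data. Event draws beyond the baseline's support and censoring draws
#' beyond the last observed time are censored at that time.
#'
#' @param object An `em_mixture_fit`.
#' @param nsim Number of replicate trials.
#' @param seed Optional seed (the caller's RNG state is restored on exit).
#' @param ... Unused.
#' @return A list of `nsim` [trial_data] objects with `true_class` set to
#'   the drawn latent class.
#' @export
simulate.em_mixture_fit <- function(object, nsim = 1, seed = NULL, ...) {
  data <- object$data
  p <- object$params
  X <- model_matrix_trial(data)
  eta_p <- drop(X %*% c(p$log_hr_pos, p$coef_pos))
  eta_n <- drop(X %*% c(p$log_hr_neg, p$coef_neg))
  cd <- censoring_distribution(data)
  n <- nrow(data)
  cov_names <- attr(data, "covariates")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  lapply(seq_len(nsim), function(b) {
    xb <- stats::rbinom(n, 1L, p$gamma)
    tt <- numeric(n)
    ip <- xb == 1L
    if (any(ip)) tt[ip] <- sample_step_ph(p$baseline_pos, eta_p[ip])
    if (any(!ip)) tt[!ip] <- sample_step_ph(p$baseline_neg, eta_n[!ip])
    cc <- sample_censoring(n, cd)
    trial_data(time = pmin(tt, cc), event = as.integer(tt <= cc),
               treatment = data$treatment,
               covariates = if (length(cov_names)) data[cov_names] else NULL,
               true_class = xb)
  })
}

#' Parametric-bootstrap variance of the class-specific log hazard ratios
#'
#' Generates `B` bootstrap trials from the fitted mixture model (see
#' [simulate.em_mixture_fit()]), refits the EM estimator on each with the
#' original initialization policy, and estimates the sampling variance of
#' the true-positive (and false-positive) treatment log hazard ratio as the
#' sample variance of the bootstrap estimates (divisor `B - 1`, computed
#' over converged refits only).
#'
#' @param fit A converged `em_mixture_fit`.
#' @param B Number of bootstrap samples (>= 2; >= 1000 recommended for a
#'   confirmatory analysis).
#' @param seed Seed for the bootstrap draws.
#' @param data Trial data the model was fitted to (defaults to the data
#'   stored in `fit`).
#' @param tol,max_iter EM control for the refits; default to the original
#'   fit's settings.
#' @return An object of class `em_bootstrap` with `draws_pos`, `draws_neg`
#'   (converged refits), `var_pos`, `var_neg`, `se_pos`, `se_neg`, `B` and
#'   `n_failed`.
#' @details More than 20% non-converged refits aborts with an error rather
#'   than silently degrading the variance estimate.
#' @export
parametric_bootstrap <- function(fit, B = 1000L, seed = NULL,
                                 data = fit$data, tol = fit$init$tol,
                                 max_iter = fit$init$max_iter) {
  stopifnot(inherits(fit, "em_mixture_fit"))
  if (B < 2) stop("B must be at least 2")
  if (!fit$converged)
    warning("bootstrapping a non-converged fit")
  samples <- simulate(fit, nsim = B, seed = seed)
  draws_pos <- draws_neg <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    rf <- tryCatch(
      suppressWarnings(em_fit(samples[[b]],
                              ppv_init = fit$init$ppv_init,
                              log_hr_init_pos = fit$init$log_hr_init_pos,
                              log_hr_init_neg = fit$init$log_hr_init_neg,
                              tol = tol, tol_rel = fit$init$tol_rel,
                              max_iter = max_iter,
                              fix_gamma = fit$init$fix_gamma,
                              fix_hr_neg = fit$init$fix_hr_neg)),
      error = function(e) NULL)
    if (!is.null(rf) && rf$converged) {
      draws_pos[b] <- rf$params$log_hr_pos
      draws_neg[b] <- rf$params$log_hr_neg
    }
  }
  ok <- !is.na(draws_pos)
  n_failed <- sum(!ok)
  if (n_failed > 0.2 * B)
    stop(sprintf("bootstrap inference unreliable: %d of %d refits failed to converge",
                 n_failed, B))
  if (sum(ok) < 2) stop("fewer than 2 converged bootstrap refits")
  structure(list(draws_pos = draws_pos[ok], draws_neg = draws_neg[ok],
                 var_pos = stats::var(draws_pos[ok]),
                 var_neg = stats::var(draws_neg[ok]),
                 se_pos = stats::sd(draws_pos[ok]),
                 se_neg = stats::sd(draws_neg[ok]),
                 estimate_pos = fit$params$log_hr_pos,
                 estimate_neg = fit$params$log_hr_neg,
                 B = as.integer(B), n_failed = as.integer(n_failed),
                 seed = seed),
            class = "em_bootstrap")
}

#' @export
print.em_bootstrap <- function(x, digits = 4, ...) {
  cat(sprintf("Parametric bootstrap: B = %d (%d refits dropped)\n", x$B, x$n_failed))
  cat(sprintf("  SE(log HR+) = %.*f, SE(log HR-) = %.*f\n",
              digits, x$se_pos, digits, x$se_neg))
  invisible(x)
}

#' Confidence intervals from a bootstrap
#'
#' Normal-quantile intervals on the log-hazard-ratio scale (the primary,
#' asymptotic form); percentile bootstrap intervals are available as a
#' non-primary diagnostic.
#'
#' @param object An `em_bootstrap`.
#' @param parm `"pos"`, `"neg"`, or both.
#' @param level Confidence level.
#' @param type `"normal"` (primary) or `"percentile"` (diagnostic).
#' @param ... Unused.
#' @return A matrix with one row per parameter and columns `lower`, `upper`.
#' @export
confint.em_bootstrap <- function(object, parm = c("pos", "neg"), level = 0.95,
                                 type = c("normal", "percentile"), ...) {
  parm <- match.arg(parm, several.ok = TRUE)
  type <- match.arg(type)
  a <- 1 - level
  out <- t(vapply(parm, function(p) {
    est <- object[[paste0("estimate_", p)]]
    if (type == "normal") {
      hw <- stats::qnorm(1 - a / 2) * object[[paste0("se_", p)]]
      c(est - hw, est + hw)
    } else {
      unname(stats::quantile(object[[paste0("draws_", p)]],
                             c(a / 2, 1 - a / 2)))
    }
  }, numeric(2)))
  colnames(out) <- c("lower", "upper")
  rownames(out) <- paste0("log_hr_", parm)
  out
}

#' Two-sided Wald test for a log hazard ratio
#'
#' Tests `H0: lambda = 0` with `z = estimate / se`, rejecting at level
#' `alpha` when `|z| >= z_{alpha/2}`, and builds the matching asymptotic
#' confidence interval `estimate +/- z_{alpha/2} * se` together with its
#' exponentiated hazard-ratio form. With a bootstrap SE this is the
#' recommended test for the targeted-therapy effect in the true-positive
#' class.
#'
#' @param estimate Log hazard ratio estimate.
#' @param se Positive standard error.
#' @param alpha Two-sided significance level in (0, 1).
#' @return An object of class `wald_test` with `estimate`, `se`, `z_stat`,
#'   `alpha`, `reject`, `ci_log` and `ci_hr`.
#' @examples
#' wald_test(log(0.7026), 0.1439, 0.05)$ci_hr
#' @export
wald_test <- function(estimate, se, alpha = 0.05) {
  if (!is.finite(se) || se <= 0) stop("se must be a positive number")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  z <- estimate / se
  zcrit <- stats::qnorm(1 - alpha / 2)
  ci_log <- c(estimate - zcrit * se, estimate + zcrit * se)
  structure(list(estimate = estimate, se = se, z_stat = z, alpha = alpha,
                 reject = abs(z) >= zcrit,
                 ci_log = ci_log, ci_hr = exp(ci_log)),
            class = "wald_test")
}

#' @export
print.wald_test <- function(x, digits = 4, ...) {
  cat(sprintf("Wald test of H0: log HR = 0 (two-sided, alpha = %g)\n", x$alpha))
  cat(sprintf("  log HR %.*f (SE %.*f), z = %.*f: %s\n", digits, x$estimate,
              digits, x$se, digits, x$z_stat,
              if (x$reject) "reject H0" else "do not reject H0"))
  cat(sprintf("  %g%% CI, HR scale: (%.*f, %.*f)\n", 100 * (1 - x$alpha),
              digits, x$ci_hr[1], digits, x$ci_hr[2]))
  invisible(x)
}

#' Target-by-treatment interaction confidence interval
#'
#' Asymptotic `100(1 - alpha)%` interval for the difference
#' `lambda_+ - lambda_-` between the treatment log hazard ratios of the
#' true-positive and false-positive classes,
#' `(est_pos - est_neg) +/- z_{alpha/2} * sqrt(var_pos + var_neg)`, the
#' variances coming from the parametric bootstrap. An interaction is
#' declared at level `alpha` when the interval excludes 0.
#'
#' @param est_pos,est_neg Class-specific log hazard ratio estimates.
#' @param var_pos,var_neg Their (bootstrap) variances; nonnegative, not
#'   both zero.
#' @param alpha Two-sided level in (0, 1).
#' @return An object of class `interaction_ci` with `estimate`, `se`,
#'   `lower`, `upper`, `alpha` and `significant`.
#' @examples
#' interaction_ci(log(0.7026), 0.259, 0.1439^2, 0.3049^2, alpha = 0.10)
#' @export
interaction_ci <- function(est_pos, est_neg, var_pos, var_neg, alpha = 0.05) {
  if (var_pos < 0 || var_neg < 0) stop("variances must be nonnegative")
  if (var_pos == 0 && var_neg == 0)
    stop("degenerate inference: both variances are zero")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  est <- est_pos - est_neg
  se <- sqrt(var_pos + var_neg)
  zcrit <- stats::qnorm(1 - alpha / 2)
  structure(list(estimate = est, se = se,
                 lower = est - zcrit * se, upper = est + zcrit * se,
                 alpha = alpha,
                 significant = (est - zcrit * se > 0) || (est + zcrit * se < 0)),
            class = "interaction_ci")
}

#' @export
print.interaction_ci <- function(x, digits = 4, ...) {
  cat(sprintf("Target-by-treatment interaction (lambda+ - lambda-): %.*f\n",
              digits, x$estimate))
  cat(sprintf("  %g%% CI: (%.*f, %.*f) -> %s at level %g\n",
              100 * (1 - x$alpha), digits, x$lower, digits, x$upper,
              if (x$significant) "significant" else "not significant", x$alpha))
  invisible(x)
}

#' @export
summary.em_mixture_fit <- function(object, bootstrap = NULL, alpha = 0.05, ...) {
  out <- list(fit = object, bootstrap = bootstrap, alpha = alpha)
  if (!is.null(bootstrap)) {
    out$wald_pos <- wald_test(object$params$log_hr_pos, bootstrap$se_pos, alpha)
    out$wald_neg <- wald_test(object$params$log_hr_neg, bootstrap$se_neg, alpha)
    out$interaction <- interaction_ci(object$params$log_hr_pos,
                                      object$params$log_hr_neg,
                                      bootstrap$var_pos, bootstrap$var_neg,
                                      alpha)
  }
  class(out) <- "summary.em_mixture_fit"
  out
}

#' @export
print.summary.em_mixture_fit <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$bootstrap)) {
    print(x$bootstrap)
    cat("True-positive class:\n")
    print(x$wald_pos)
    cat("False-positive class:\n")
    print(x$wald_neg)
    print(x$interaction)
  }
  invisible(x)
}

#' One-call analysis of an enrichment trial
#'
#' Convenience wrapper running the full recommended analysis on one trial:
#' the naive Cox fit with model-based Wald inference, the EM mixture fit
#' with the validation-study PPV, the parametric bootstrap, bootstrap-based
#' Wald inference for both latent classes, and the target-by-treatment
#' interaction interval.
#'
#' @param data A [trial_data].
#' @param ppv Validation-study PPV of the diagnostic.
#' @param B Bootstrap samples (>= 1000 recommended).
#' @param alpha Two-sided significance level.
#' @param seed Seed for the bootstrap.
#' @param protocol_hr Protocol-specified hazard ratio used to initialize
#'   the EM (default 1).
#' @return An object of class `enrichment_analysis`: a list with the two
#'   fits, the bootstrap, the Wald tests and the interaction interval.
#' @seealso [write_analysis_report()] to serialize the result.
#' @export
analyze_trial <- function(data, ppv, B = 1000L, alpha = 0.05, seed = NULL,
                          protocol_hr = 1) {
  naive <- fit_naive_cox(data)
  # lambda- is freed here: the interaction analysis needs both class effects
  em <- em_fit(data, ppv_init = ppv, log_hr_init_pos = log(protocol_hr),
               fix_hr_neg = FALSE)
  boot <- parametric_bootstrap(em, B = B, seed = seed)
  structure(list(
    naive = naive,
    naive_wald = wald_test(naive$log_hr, naive$se_model, alpha),
    em = em,
    bootstrap = boot,
    em_wald_pos = wald_test(em$params$log_hr_pos, boot$se_pos, alpha),
    em_wald_neg = wald_test(em$params$log_hr_neg, boot$se_neg, alpha),
    interaction = interaction_ci(em$params$log_hr_pos, em$params$log_hr_neg,
                                 boot$var_pos, boot$var_neg, alpha),
    alpha = alpha, seed = seed), class = "enrichment_analysis")
}

#' @export
print.enrichment_analysis <- function(x, digits = 4, ...) {
  cat("== Naive Cox analysis (ignores misclassification) ==\n")
  print(x$naive, digits = digits)
  print(x$naive_wald, digits = digits)
  cat("\n== Misclassification-adjusted EM analysis ==\n")
  print(x$em, digits = digits)
  print(x$bootstrap, digits = digits)
  cat("True-positive class:\n")
  print(x$em_wald_pos, digits = digits)
  cat("False-positive class:\n")
  print(x$em_wald_neg, digits = digits)
  print(x$interaction, digits = digits)
  invisible(x)
}

#' Serialize an analysis as a flat JSON report
#'
#' @param x An `enrichment_analysis` from [analyze_trial()].
#' @param path Output file path.
#' @return Invisibly, the report list.
#' @export
write_analysis_report <- function(x, path) {
  stopifnot(inherits(x, "enrichment_analysis"))
  rep <- list(
    alpha = x$alpha,
    seed = x$seed,
    naive_hr = exp(x$naive$log_hr),
    naive_log_hr = x$naive$log_hr,
    naive_se = x$naive$se_model,
    naive_ci_hr_lower = x$naive_wald$ci_hr[1],
    naive_ci_hr_upper = x$naive_wald$ci_hr[2],
    naive_reject = x$naive_wald$reject,
    em_gamma = x$em$params$gamma,
    em_hr_pos = exp(x$em$params$log_hr_pos),
    em_log_hr_pos = x$em$params$log_hr_pos,
    em_se_pos = x$bootstrap$se_pos,
    em_ci_hr_pos_lower = x$em_wald_pos$ci_hr[1],
    em_ci_hr_pos_upper = x$em_wald_pos$ci_hr[2],
    em_reject_pos = x$em_wald_pos$reject,
    em_hr_neg = exp(x$em$params$log_hr_neg),
    em_log_hr_neg = x$em$params$log_hr_neg,
    em_se_neg = x$bootstrap$se_neg,
    interaction_lower = x$interaction$lower,
    interaction_upper = x$interaction$upper,
    interaction_significant = x$interaction$significant,
    bootstrap_B = x$bootstrap$B,
    bootstrap_n_failed = x$bootstrap$n_failed,
    em_converged = x$em$converged,
    em_n_iter = x$em$n_iter)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  invisible(rep)
}
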