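#' Define a simulation scenario for an enrichment-design trial
#'
#' A scenario fixes the design of one simulated trial: patients are test
#' positive for the molecular target with latent true status drawn
#' Bernoulli(`ppv`), randomized 1:1 to targeted therapy or control, and
#' followed until a class-specific Weibull proportional-hazards event time
#' or an independent censoring time calibrated to an overall censoring
#' proportion.
#'
#' The event hazard for a patient of latent class c on arm z is
#' `shape * t^(shape-1) * baseline_rate * exp(log(hr_c) * z)`; `shape = 1`
#' gives the exponential model used in the main simulation study, and
#' `shape_pos = 2` gives the Weibull misspecification scenario.
#'
#' @param n_per_arm Number of patients per treatment arm.
#' @param ppv Positive predictive value of the diagnostic (probability that
#'   a test-positive patient truly carries the target), in (0, 1].
#' @param hr_pos Hazard ratio of targeted therapy vs control in true-positive
#'   patients (`exp(lambda_+)`).
#' @param hr_neg Hazard ratio in false-positive patients; 1 encodes a
#'   therapy that is ineffective without the target.
#' @param censor_rate Target marginal censoring proportion, in [0, 1).
#' @param baseline_rate_pos,baseline_rate_neg Baseline hazard scale per class.
#' @param shape_pos,shape_neg Weibull shape per class (1 = exponential).
#' @param seed Master seed for this scenario; [simulate_trial()] is a pure
#'   function of the scenario, including its seed.
#' @return An object of class `trial_scenario`.
#' @examples
#' sp <- trial_scenario(n_per_arm = 50, ppv = 0.7, hr_pos = 0.7, seed = 1)
#' d <- simulate_trial(sp)
#' mean(d$true_class)
#' @export
trial_scenario <- function(n_per_arm, ppv, hr_pos, hr_neg = 1,
                           censor_rate = 0, baseline_rate_pos = 1,
                           baseline_rate_neg = 1, shape_pos = 1,
                           shape_neg = 1, seed = 1L) {
  stopifnot(n_per_arm >= 1, ppv > 0, ppv <= 1,
            hr_pos > 0, hr_neg > 0,
            censor_rate >= 0, censor_rate < 1,
            baseline_rate_pos > 0, baseline_rate_neg > 0,
            shape_pos > 0, shape_neg > 0)
  structure(list(n_per_arm = as.integer(n_per_arm), ppv = ppv,
                 hr_pos = hr_pos, hr_neg = hr_neg,
                 censor_rate = censor_rate,
                 baseline_rate_pos = baseline_rate_pos,
                 baseline_rate_neg = baseline_rate_neg,
                 shape_pos = shape_pos, shape_neg = shape_neg,
                 seed = as.integer(seed)),
            class = "trial_scenario")
}

#' @export
print.trial_scenario <- function(x, ...) {
  cat("Enrichment-trial scenario\n")
  cat(sprintf("  n per arm: %d, PPV: %g, HR+: %g, HR-: %g\n",
              x$n_per_arm, x$ppv, x$hr_pos, x$hr_neg))
  cat(sprintf("  censoring: %g, shapes: (%g, %g), rates: (%g, %g), seed: %d\n",
              x$censor_rate, x$shape_pos, x$shape_neg,
              x$baseline_rate_pos, x$baseline_rate_neg, x$seed))
  invisible(x)
}

#' Read a scenario from a flat YAML config file
#'
#' The file holds the [trial_scenario()] fields as top-level keys; missing
#' keys fall back to the constructor defaults.
#'
#' @param path Path to a YAML file.
#' @return A `trial_scenario`.
#' @export
read_scenario <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(trial_scenario))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown scenario fields: ", paste(bad, collapse = ", "))
  do.call(trial_scenario, vals)
}

# P(censored) for one (class, arm) cell under exponential censoring with
# rate theta and a Weibull PH event-time law.
cell_censor_prob <- function(theta, rate, shape, loghr, z) {
  r <- rate * exp(loghr * z)
  if (shape == 1) return(theta / (theta + r))
  f <- function(t) theta * exp(-theta * t - r * t^shape)
  stats::integrate(f, 0, Inf, rel.tol = 1e-9)$value
}

# Exponential censoring rate theta such that the marginal censoring
# probability (over latent class and arm) equals censor_rate.
calibrate_censoring <- function(spec) {
  if (spec$censor_rate == 0) return(0)
  marginal <- function(theta) {
    p <- c(spec$ppv / 2, spec$ppv / 2, (1 - spec$ppv) / 2, (1 - spec$ppv) / 2)
    cells <- rbind(c(spec$baseline_rate_pos, spec$shape_pos, log(spec$hr_pos), 1),
                   c(spec$baseline_rate_pos, spec$shape_pos, log(spec$hr_pos), 0),
                   c(spec$baseline_rate_neg, spec$shape_neg, log(spec$hr_neg), 1),
                   c(spec$baseline_rate_neg, spec$shape_neg, log(spec$hr_neg), 0))
    sum(p * vapply(seq_len(4), function(i)
      cell_censor_prob(theta, cells[i, 1], cells[i, 2], cells[i, 3], cells[i, 4]),
      numeric(1)))
  }
  lo <- 1e-8
  hi <- 1e4
  flo <- marginal(lo) - spec$censor_rate
  fhi <- marginal(hi) - spec$censor_rate
  if (flo * fhi > 0)
    stop(sprintf("censoring calibration failed: no root in [%g, %g]", lo, hi),
         call. = FALSE)
  stats::uniroot(function(th) marginal(th) - spec$censor_rate,
                 lower = lo, upper = hi, tol = 1e-10)$root
}

#' Simulate one enrichment-design trial
#'
#' Draws a trial according to a [trial_scenario()]: latent true target
#' status i.i.d. Bernoulli(`ppv`); exactly `n_per_arm` patients per arm by
#' permuted 1:1 assignment; event times from the class-specific Weibull
#' proportional-hazards model; independent exponential censoring with rate
#' calibrated so the marginal censoring probability equals `censor_rate`
#' (no censoring mechanism at all when `censor_rate = 0`).
#'
#' The draw is a pure function of the scenario: the same settings (including
#' `seed`) always yields the same data. The caller's RNG state is left
#' untouched.
#'
#' @param spec A [trial_scenario()].
#' @return A [trial_data] with `true_class` recorded.
#' @export
simulate_trial <- function(spec) {
  stopifnot(inherits(spec, "trial_scenario"))
  theta <- calibrate_censoring(spec)
  n <- 2L * spec$n_per_arm
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  x <- stats::rbinom(n, 1L, spec$ppv)
  z <- sample(rep(c(0L, 1L), each = spec$n_per_arm))
  rate <- ifelse(x == 1L, spec$baseline_rate_pos, spec$baseline_rate_neg)
  shape <- ifelse(x == 1L, spec$shape_pos, spec$shape_neg)
  loghr <- ifelse(x == 1L, log(spec$hr_pos), log(spec$hr_neg))
  tt <- (stats::rexp(n) / (rate * exp(loghr * z)))^(1 / shape)
  if (theta > 0) {
    cc <- stats::rexp(n, rate = theta)
    trial_data(time = pmin(tt, cc), event = as.integer(tt <= cc),
               treatment = z, true_class = x)
  } else {
    trial_data(time = tt, event = rep(1L, n), treatment = z, true_class = x)
  }
}
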