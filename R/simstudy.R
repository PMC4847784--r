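# Deterministic 31-bit hash of a scenario's fields, so that replicate
# seed streams depend on the scenario itself and not on its position in a
# grid (worker-count and grid-order invariance).
scenario_hash <- function(spec) {
  s <- paste(vapply(spec, function(v) format(v, digits = 15), character(1)),
             collapse = "|")
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

replicate_seed <- function(spec, seed, r) {
  as.integer((scenario_hash(spec) + seed + r * 10007) %% 2147483647)
}

#' Monte-Carlo evaluation of one simulation scenario
#'
#' Simulates `n_reps` independent trials from `spec` and analyzes each with
#' the naive Cox model (model-based Wald inference) and the EM mixture
#' estimator (parametric-bootstrap Wald inference when `B >= 2`), then
#' aggregates relative bias, coverage of the true hazard ratio in
#' true-positive patients, and the rejection rate of the two-sided level
#' `alpha` test (empirical size when `hr_pos = 1`, power otherwise).
#'
#' The EM is initialized at the scenario's own design values, mirroring the
#' recommended practice of starting from the validation-study PPV and the
#' protocol hazard ratio. Replicate seeds are derived from the scenario's
#' fields and `seed`, so results do not depend on grid order or worker
#' count. Replicates where a requested fit fails or does not converge are
#' excluded from the aggregates and counted in `n_nonconverged`.
#'
#' @param spec A [trial_scenario()].
#' @param n_reps Number of simulated trials (>= 2).
#' @param B Bootstrap samples per replicate for EM inference; set `B = 0`
#'   to skip the bootstrap (bias and naive-test metrics only).
#' @param alpha Two-sided significance level.
#' @param seed Integer master seed for the study.
#' @param methods Which analyses to run (`"naive"`, `"em"`, or both).
#' @return An object of class `scenario_result` with the aggregate fields
#'   (`rel_bias_naive`, `rel_bias_em` in percent, `coverage_*`,
#'   `reject_rate_*`, `mean_gamma_hat`, `n_nonconverged`) and the raw
#'   per-replicate estimates in `$reps`.
#' @export
run_scenario <- function(spec, n_reps, B = 0L, alpha = 0.05, seed = 1L,
                         methods = c("naive", "em")) {
  stopifnot(inherits(spec, "trial_scenario"), n_reps >= 2, B == 0 || B >= 2)
  methods <- match.arg(methods, several.ok = TRUE)
  do_naive <- "naive" %in% methods
  do_em <- "em" %in% methods
  ppv_init <- min(1 - 1e-6, max(1e-6, spec$ppv))
  reps <- data.frame(rep = seq_len(n_reps), naive_hr = NA_real_,
                     naive_cover = NA, naive_reject = NA,
                     em_hr = NA_real_, em_gamma = NA_real_,
                     em_cover = NA, em_reject = NA, ok = FALSE)
  for (r in seq_len(n_reps)) {
    rs <- replicate_seed(spec, seed, r)
    spec_r <- spec
    spec_r$seed <- rs
    dat <- simulate_trial(spec_r)
    ok <- TRUE
    if (do_naive) {
      nf <- tryCatch(fit_naive_cox(dat), error = function(e) NULL)
      if (is.null(nf) || !nf$converged) ok <- FALSE
      else {
        wt <- wald_test(nf$log_hr, nf$se_model, alpha)
        reps$naive_hr[r] <- exp(nf$log_hr)
        reps$naive_cover[r] <- wt$ci_hr[1] <= spec$hr_pos &&
          spec$hr_pos <= wt$ci_hr[2]
        reps$naive_reject[r] <- wt$reject
      }
    }
    if (do_em) {
      ef <- tryCatch(
        suppressWarnings(em_fit(dat, ppv_init = ppv_init,
                                log_hr_init_pos = log(spec$hr_pos),
                                log_hr_init_neg = 0)),
        error = function(e) NULL)
      if (is.null(ef) || !ef$converged) ok <- FALSE
      else {
        reps$em_hr[r] <- exp(ef$params$log_hr_pos)
        reps$em_gamma[r] <- ef$params$gamma
        if (B >= 2) {
          bt <- tryCatch(
            parametric_bootstrap(ef, B = B,
                                 seed = (rs + 500009) %% 2147483647),
            error = function(e) NULL)
          if (is.null(bt)) ok <- FALSE
          else {
            wt <- wald_test(ef$params$log_hr_pos, bt$se_pos, alpha)
            reps$em_cover[r] <- wt$ci_hr[1] <= spec$hr_pos &&
              spec$hr_pos <= wt$ci_hr[2]
            reps$em_reject[r] <- wt$reject
          }
        }
      }
    }
    reps$ok[r] <- ok
  }
  ok <- reps$ok
  agg <- function(v) if (any(ok) && !all(is.na(v[ok]))) mean(v[ok]) else NA_real_
  structure(list(
    spec = spec, n_reps = as.integer(n_reps), B = as.integer(B),
    alpha = alpha,
    mean_gamma_hat = agg(reps$em_gamma),
    rel_bias_naive = 100 * (agg(reps$naive_hr) - spec$hr_pos) / spec$hr_pos,
    rel_bias_em = 100 * (agg(reps$em_hr) - spec$hr_pos) / spec$hr_pos,
    coverage_naive = agg(reps$naive_cover),
    coverage_em = agg(reps$em_cover),
    reject_rate_naive = agg(reps$naive_reject),
    reject_rate_em = agg(reps$em_reject),
    n_nonconverged = sum(!ok),
    reps = reps), class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("Scenario (PPV %g, HR+ %g, CR %g, n/arm %d): %d reps, B = %d\n",
              x$spec$ppv, x$spec$hr_pos, x$spec$censor_rate,
              x$spec$n_per_arm, x$n_reps, x$B))
  cat(sprintf("  rel bias %%: naive %.2f, EM %.2f | mean gamma-hat %.3f\n",
              x$rel_bias_naive, x$rel_bias_em, x$mean_gamma_hat))
  cat(sprintf("  coverage: naive %.3f, EM %.3f | reject rate: naive %.3f, EM %.3f\n",
              x$coverage_naive, x$coverage_em,
              x$reject_rate_naive, x$reject_rate_em))
  if (x$n_nonconverged > 0)
    cat(sprintf("  %d replicate(s) excluded (non-convergence)\n", x$n_nonconverged))
  invisible(x)
}

#' @export
as.data.frame.scenario_result <- function(x, ...) {
  data.frame(n_per_arm = x$spec$n_per_arm, ppv = x$spec$ppv,
             hr_pos = x$spec$hr_pos, hr_neg = x$spec$hr_neg,
             censor_rate = x$spec$censor_rate,
             shape_pos = x$spec$shape_pos, shape_neg = x$spec$shape_neg,
             n_reps = x$n_reps, B = x$B,
             mean_gamma_hat = x$mean_gamma_hat,
             rel_bias_naive = x$rel_bias_naive, rel_bias_em = x$rel_bias_em,
             coverage_naive = x$coverage_naive, coverage_em = x$coverage_em,
             reject_rate_naive = x$reject_rate_naive,
             reject_rate_em = x$reject_rate_em,
             n_nonconverged = x$n_nonconverged)
}

#' Run a grid of simulation scenarios
#'
#' Applies [run_scenario()] to each scenario of a grid. Per-scenario seed
#' streams are derived from the scenario's own fields, so the results are
#' identical whatever the grid order or the number of workers.
#'
#' @param grid A list of [trial_scenario()] objects (see [paper_grid()]).
#' @param n_reps,B,alpha,seed,methods Passed to [run_scenario()].
#' @param workers Number of local worker processes (forked via the
#'   `parallel` package when > 1).
#' @return A list of `scenario_result`, one per scenario, in grid order.
#' @seealso [results_long()] for a tidy long table,
#'   [summarize_bias_table()] and friends for the wide layouts.
#' @export
run_grid <- function(grid, n_reps, B = 0L, alpha = 0.05, seed = 1L,
                     methods = c("naive", "em"), workers = 1L) {
  stopifnot(length(grid) >= 1)
  runner <- function(sp) run_scenario(sp, n_reps = n_reps, B = B,
                                      alpha = alpha, seed = seed,
                                      methods = methods)
  if (workers > 1L && requireNamespace("parallel", quietly = TRUE)) {
    parallel::mclapply(grid, runner, mc.cores = workers)
  } else {
    lapply(grid, runner)
  }
}

#' Scenario grids of the reference simulation design
#'
#' Builds the factorial grid used in the simulation study: PPV in 0.5-0.9
#' by 0.1, censoring proportion 0-0.4 by 0.1, 300/600/900 patients per arm,
#' and hazard ratios 0.70/0.75/0.80/0.85 for power (300 combinations) or
#' hazard ratio 1 for size (75 combinations); false-positive hazard ratio 1
#' and exponential event times throughout.
#'
#' @param type `"power"` or `"size"`.
#' @param ppv,censor_rate,n_per_arm,hr Optional subsets of the factors.
#' @return A list of [trial_scenario()] objects.
#' @export
paper_grid <- function(type = c("power", "size"),
                       ppv = c(0.5, 0.6, 0.7, 0.8, 0.9),
                       censor_rate = c(0, 0.1, 0.2, 0.3, 0.4),
                       n_per_arm = c(300, 600, 900),
                       hr = c(0.70, 0.75, 0.80, 0.85)) {
  type <- match.arg(type)
  if (type == "size") hr <- 1
  cells <- expand.grid(ppv = ppv, censor_rate = censor_rate,
                       n_per_arm = n_per_arm, hr = hr,
                       KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(cells)), function(i)
    trial_scenario(n_per_arm = cells$n_per_arm[i], ppv = cells$ppv[i],
                   hr_pos = cells$hr[i], hr_neg = 1,
                   censor_rate = cells$censor_rate[i], seed = 1L))
}

#' Tidy long-format table of grid results
#'
#' @param results A list of `scenario_result` (from [run_grid()]).
#' @return A data frame with one row per scenario x method x metric.
#' @export
results_long <- function(results) {
  wide <- do.call(rbind, lapply(results, as.data.frame))
  keys <- c("n_per_arm", "ppv", "hr_pos", "censor_rate")
  metrics <- list(naive = c(rel_bias = "rel_bias_naive",
                            coverage = "coverage_naive",
                            reject_rate = "reject_rate_naive"),
                  em = c(rel_bias = "rel_bias_em",
                         coverage = "coverage_em",
                         reject_rate = "reject_rate_em"))
  out <- do.call(rbind, lapply(names(metrics), function(m) {
    do.call(rbind, lapply(names(metrics[[m]]), function(met) {
      cbind(wide[keys], method = m, metric = met,
            value = wide[[metrics[[m]][[met]]]])
    }))
  }))
  rownames(out) <- NULL
  out
}

# shared wide pivot: rows (n, HR, CR), columns PPV x (naive, EM)
pivot_wide <- function(results, field_naive, field_em, digits, rows_hr = TRUE) {
  wide <- do.call(rbind, lapply(results, as.data.frame))
  key_cols <- if (rows_hr) c("n_per_arm", "hr_pos", "censor_rate")
              else c("n_per_arm", "censor_rate")
  rows <- unique(wide[key_cols])
  rows <- rows[do.call(order, rows), , drop = FALSE]
  ppvs <- sort(unique(wide$ppv))
  out <- rows
  names(out) <- c("n", if (rows_hr) "HR", "CR")
  for (pv in ppvs) {
    nv <- ev <- rep(NA_real_, nrow(rows))
    for (i in seq_len(nrow(rows))) {
      sel <- wide$ppv == pv &
        wide$n_per_arm == rows$n_per_arm[i] &
        wide$censor_rate == rows$censor_rate[i]
      if (rows_hr) sel <- sel & wide$hr_pos == rows$hr_pos[i]
      if (any(sel)) {
        nv[i] <- wide[[field_naive]][which(sel)[1]]
        ev[i] <- wide[[field_em]][which(sel)[1]]
      }
    }
    out[[sprintf("Naive_%g", pv)]] <- round(nv, digits)
    out[[sprintf("EM_%g", pv)]] <- round(ev, digits)
  }
  if (anyNA(out[-seq_along(key_cols)]))
    warning("missing scenario cells; emitted as NA")
  raw <- out
  attr(out, "raw") <- raw
  rownames(out) <- NULL
  out
}

#' Wide summary tables in the reference layout
#'
#' Re-shape grid results into the wide layouts of the simulation report:
#' rows indexed by sample size, hazard ratio and censoring rate, and paired
#' naive/EM columns per PPV. Relative bias is rounded to 2 decimals,
#' proportions to 3; the unrounded table is attached as `attr(x, "raw")`.
#'
#' @param results A list of `scenario_result`.
#' @param metric For `summarize_bias_table()`: `"bias"` (relative bias in
#'   percent) or `"coverage"`.
#' @return A data frame in the wide layout.
#' @export
summarize_bias_table <- function(results, metric = c("bias", "coverage")) {
  metric <- match.arg(metric)
  if (metric == "bias")
    pivot_wide(results, "rel_bias_naive", "rel_bias_em", 2)
  else
    pivot_wide(results, "coverage_naive", "coverage_em", 3)
}

#' @rdname summarize_bias_table
#' @export
summarize_power_table <- function(results) {
  pivot_wide(results, "reject_rate_naive", "reject_rate_em", 3)
}

#' @rdname summarize_bias_table
#' @export
summarize_size_table <- function(results) {
  pivot_wide(results, "reject_rate_naive", "reject_rate_em", 3, rows_hr = FALSE)
}
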