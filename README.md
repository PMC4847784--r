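# emcox

Misclassification-adjusted Cox models for enrichment-design clinical
trials.

## The problem

Enrichment designs screen every candidate patient with a companion
diagnostic and randomize only the test-positive ones between a targeted
therapy and a concurrent control. Because no diagnostic has a perfect
positive predictive value (PPV), a fraction of the randomized patients do
not actually carry the molecular target the therapy is aimed at. A
standard Cox proportional-hazards analysis of such a trial mixes true and
false positives and attenuates the treatment effect toward a hazard ratio
of 1 — at PPV 0.5 the attenuation can approach 20% of the true effect —
which costs power and can sink an effective therapy.

`emcox` is for trial statisticians who have a PPV estimate from a
diagnostic validation study and want the treatment effect *in the
patients who truly carry the target*. It models the randomized population
as a two-latent-class Cox mixture with a shared baseline hazard:

- latent target status `X_i ~ Bernoulli(gamma)`, with `gamma` the PPV;
- hazard `h0(t) * exp(lambda_+ z)` for true positives and
  `h0(t) * exp(lambda_- z)` for false positives (`z` = treatment arm;
  `lambda_-` is pinned at 0 by default — a targeted therapy is designed
  to be inert without the target — and can be freed for interaction
  analyses).

Estimation is by an EM algorithm: the E-step computes each patient's
posterior probability of truly carrying the target; the M-step updates
`gamma` (posterior mean), the class log hazard ratios
(posterior-weighted Cox partial likelihood, Breslow ties) and the shared
baseline (mixture-weighted Breslow estimator). Standard errors come from
a parametric bootstrap that re-simulates trials from the fitted mixture
and refits; tests and confidence intervals are Wald-type, including the
target-by-treatment interaction `lambda_+ - lambda_-`. A trial simulator
and a Monte-Carlo harness reproduce the estimator's operating
characteristics (bias, coverage, size, power) against the naive analysis.

## Worked example

Simulate a trial of 600 patients (PPV 0.75, true hazard ratio 0.7 in
carriers, 30% censoring) and run the full analysis:

```r
library(emcox)
sp <- trial_scenario(n_per_arm = 300, ppv = 0.75, hr_pos = 0.7, hr_neg = 1,
                     censor_rate = 0.3, seed = 9)
d  <- simulate_trial(sp)
an <- analyze_trial(d, ppv = 0.75, B = 1000, alpha = 0.05, seed = 1,
                    protocol_hr = 0.7)
an
```

```
== Naive Cox analysis (ignores misclassification) ==
Cox proportional-hazards fit (Breslow ties)
  log HR (treatment): -0.2653  [HR 0.7670]
  model-based SE: 0.0987
...
== Misclassification-adjusted EM analysis ==
Misclassification-adjusted mixture Cox model (EM)
  estimated PPV (gamma): 0.7471
  true-positive class:  log HR -0.3471  [HR 0.7067]
  false-positive class: log HR -0.0138  [HR 0.9863]
Parametric bootstrap: B = 1000 (0 refits dropped)
  SE(log HR+) = 0.1324, SE(log HR-) = 0.3553
True-positive class:
  log HR -0.3471 (SE 0.1324), z = -2.6227: reject H0
  95% CI, HR scale: (0.5452, 0.9160)
Target-by-treatment interaction (lambda+ - lambda-): -0.3333
  95% CI: (-1.0765, 0.4099) -> not significant at level 0.05
```

The naive analysis reports hazard ratio 0.767 — attenuated from the true
0.7 by the 25% of patients without the target. The adjusted fit recovers
0.707 for the true-positive class (95% CI 0.545–0.916), estimates the PPV
at 0.747 from the trial itself, finds no effect in the false-positive
class (truth: none), and the wider bootstrap SE honestly prices the extra
uncertainty from the latent classes. Single functions are available for
each piece: `em_fit()`, `parametric_bootstrap()`, `wald_test()`,
`interaction_ci()`, `fit_naive_cox()`, `read_trial()`/`write_trial()`.

Monte-Carlo performance, e.g. bias and size at one design point:

```r
rs <- run_scenario(trial_scenario(n_per_arm = 300, ppv = 0.5, hr_pos = 0.85,
                                  censor_rate = 0.1, seed = 1),
                   n_reps = 1000, B = 0, seed = 17)
rs$rel_bias_naive   # ~ +9   (% bias of the naive hazard ratio)
rs$rel_bias_em      # ~ +1   (% bias of the adjusted estimator)
```

See the vignette (`vignettes/mixture-cox-enrichment.Rmd`) for the model,
the identifiability restriction behind the shared baseline, the stopping
rule, and known limitations.

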