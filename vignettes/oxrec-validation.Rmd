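---
title: "Validating and recalibrating OxRec-style recidivism risk models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating and recalibrating OxRec-style recidivism risk models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxrecal)
```

## The model

OxRec estimates the probability that a person released from prison is
reimprisoned for a violent crime within a fixed horizon (one year here) from
routinely collected predictors: criminal history (length of incarceration in
four bands, violent index offense, previous violent crime), sociodemographic
factors (sex, age, civil status, education, employment, income) and clinical
factors (alcohol misuse, drug misuse, any mental disorder, any severe mental
disorder). The predicted risk takes the form

$$\mathrm{risk} = 1 - S^{\exp(\lambda \cdot LP)}, \qquad
  LP = \sum_k \beta_k \, RF_k + \sum_j \beta_j m_j,$$

where $S$ is the baseline survival (the event-free probability at $LP = 0$),
$\beta_k$ the predictor weights, and $\lambda$ a multiplicative
recalibration shape (1 in the original model). Predictors unavailable in a
new setting — typically immigrant status and neighborhood deprivation, which
come from national registries — are "averaged out" by mean imputation:
every individual receives the derivation-sample mean $m_j$, contributing the
constant $\sum_j \beta_j m_j$ to every linear predictor. With the standard
values ($\beta = -0.0348$, $m = 0.3075$; $\beta = 0.0259$, $m = 0.39$) this
offset is $-0.0006$.

The outcome is treated as a fixed-horizon binary event and validation is
complete-case: individuals whose outcome could not be ascertained are
excluded before any metric is computed. Censoring machinery is deliberately
out of scope — the quantity being validated is a one-year probability.

A central algebraic fact drives the whole package: on the complementary
log-log scale the model is exactly linear,

$$\operatorname{cloglog}(\mathrm{risk}) = \log(-\log S) + \lambda \cdot LP.$$

Every updating step is therefore fitted as a binary regression with a
cloglog link, and the fitted intercept and slope map back *exactly* into the
$(S, \lambda)$ parameterization via $S' = \exp(-\exp(a))$ and
$\lambda' = b$. A logistic-scale recalibration would not round-trip into the
published closed form; this is the package's central modeling decision.

## The validation metric suite

`build_report()` bundles the measures a TRIPOD-style external validation
reports:

* **Brier score** — mean squared difference between predicted risk and
  outcome; for a calibrated predictor its expectation is
  $\mathbb{E}[r(1-r)]$, and the constant-prevalence predictor scores
  $p(1-p)$.
* **AUC / c-index** — Mann–Whitney concordance computed from midranks
  (algebraically identical to trapezoidal ROC integration, ties counting
  one half). The confidence interval uses the DeLong variance by default; a
  seeded bootstrap percentile interval is available. The CI method is a
  package choice — validation reports rarely state one.
* **Calibration-in-the-large (CITL)** — intercept of a logistic regression
  of the outcome on the fixed offset $\operatorname{logit}(r)$ with slope
  pinned at 1; **calibration slope** — the slope of the same regression
  with a free intercept. Pinned-then-free is the standard hierarchy
  matching how the two are reported separately.
* **E:O ratio** — $\sum r_i / \sum y_i$.
* **Calibration bins** — individuals ranked by predicted risk and cut into
  10 equal-count quantile groups ("deciles"), boundary ties resolved by
  stable rank order.
* **Threshold tables** — at each cutoff (default 5/10/15/20%), an
  individual is classified positive when $r \ge t$ (the boundary counts as
  positive; a fixed rule is needed for reproducibility), and sensitivity,
  specificity, PPV and NPV carry Wilson score intervals, which behave at
  boundary counts. Percentages are rounded to whole percent only in the
  Markdown rendering, never in stored values.

## The updating ladder

Model updating is incremental — each step is only warranted when the
previous one leaves performance inadequate:

1. **simple** — apply the original coefficients unchanged and report.
2. **baseline** — refit only the intercept (offset $\lambda \cdot LP$
   fixed): a new $S'$, rank order untouched.
3. **slope** — refit intercept and slope: a new $S'$ and a single
   multiplicative value $\lambda'$ applied to the *whole* linear predictor,
   including the imputed constant. Still a monotone transform, so the AUC
   is unchanged to machine precision.
4. **selective** — free dummy coefficients for one predictor whose effect
   differs between populations (length of incarceration by default), plus a
   free intercept and a free slope on the partial linear predictor. This
   can change the rank order of risks, so discrimination may move. The
   refitted dummies are stored divided by $\lambda'$ so they sit inside the
   $\lambda'$-multiplied bracket of the closed form, mirroring how
   recalibrated models are printed. Full re-derivation of all predictor
   coefficients is a last resort and is not implemented.

The stages are nested on the cloglog scale, so the in-sample log-likelihood
is non-decreasing down the ladder (a property test asserts this). Fitting
uses iteratively reweighted least squares (`stats::glm`) with a deviance
tolerance of 1e-10 and at most 100 iterations; non-convergence and apparent
separation (|coefficient| > 20) are hard errors. Updating is in-sample (fit
and report on the same cohort), which mirrors how small validation studies
proceed.

## The synthetic cohort generator

No individual-level validation data are publicly available, so the package
ships a generator that emulates the Tajik prison-release validation cohort:

* **Case-mix** — `tajik_marginals()` reproduces the published baseline
  table as counts over 970 (13% female, 63% violent index offense, 8%
  previous violent crime, 40% unmarried, 64% employed, 37% alcohol misuse,
  9% drug misuse, 48% any mental disorder, 5% severe mental disorder, and
  an inverted length-of-incarceration distribution with 86% serving two
  years or more). Age bands (0.30/0.35/0.25/0.10) are a package choice
  matching the published median 35 and IQR 28–43, which the table gives
  only as summaries. Predictors are sampled *independently*: only
  marginals are published, so no correlation structure is imposed — which
  also means the generator understates any real-world collinearity between,
  say, substance misuse and mental disorder. Passing tests on this
  generator therefore demonstrate statistical correctness of the machinery,
  not performance on real cohorts.
* **True model** — the bundled `"sweden-synthetic"` coefficient set. The
  original Swedish weights are not public here, so these are synthetic but
  plausible values (signs and magnitudes a criminological reader would
  recognize), with the published baseline survival $S = 0.7992$ and the two
  published imputed terms. The free weights were fixed once so that the
  mean predicted risk under the Tajik case-mix is ≈ 0.15, the observed
  one-year incidence; this makes the default generator reproduce the
  study's event flow (about 145 events among 970).
* **Distortions** — outcomes are drawn Bernoulli from
  $1 - \exp(-\exp(\log(-\log S) + \delta_0 + \delta_1 \lambda LP^*))$,
  where $\delta_0$ shifts the baseline on the cloglog scale, $\delta_1$
  distorts the slope, and coefficient overrides alter individual predictor
  effects in $LP^*$ — the three axes along which external validity breaks
  (incidence, overall effect strength, individual effects). True risks are
  returned out-of-band so tests can compute oracle quantities without
  polluting the cohort file format.
* **Missingness** — `apply_outcome_missingness()` removes a seeded random
  subset of exactly `round(rate * n)` outcomes, emulating loss to follow-up
  (33 of 1,003 in the study); the 100-events rule of thumb is exposed as
  `check_events_rule()`.

All randomness flows from explicit integer seeds through `withr::with_seed`;
no function touches the global RNG state.

## Numerical choices

* Risks are clipped to $[10^{-10}, 1-10^{-10}]$ before any logit/cloglog
  transform. No boundary risk arises from finite linear predictors, but
  file-supplied risks might sit on the boundary.
* Linear predictors are quantized at $10^{-9}$. Covariate patterns whose
  coefficient sums are mathematically equal would otherwise differ by a few
  ulps depending on summation path, turning exact ties into phantom
  near-ties whose ordering flips under monotone reparameterization; the
  quantum is far below any meaningful coefficient difference and far above
  double-precision summation error, and restores exact AUC invariance
  under baseline/slope recalibration.
* $\operatorname{cloglog}(r)$ loses precision as $r \to 1$ (catastrophic
  cancellation in $1 - r$); the linearity identity is therefore asserted
  away from the boundary.
* Wilson interval bounds are clamped to contain the point estimate, which
  float rounding can violate by ~$10^{-17}$.
* Quantile binning assigns ranks stably (ties keep input order), so bin
  membership is deterministic.

## Problem sizes and Monte-Carlo conventions

Simulation-based checks use cohorts of 50,000 with 20 seeds for
calibration-null and parameter-recovery properties, and 970–20,000 for
structural checks. Monte-Carlo acceptance bands are evaluated on the
across-seed mean: per-seed sampling noise at $n = 50{,}000$ (e.g. an E:O
standard deviation of ≈ 0.011, slope ≈ 0.02) would otherwise trip tight
bands by chance alone across 20 seeds. Recovery of selectively re-estimated
dummies is asserted within two Monte-Carlo standard errors of the
across-seed mean; all three dummies share the noise of the small reference
band (under six months, ~0.3% of the cohort), which dominates their
standard errors.

A note on one bundled scenario: when a slope distortion is present, an
intercept-only baseline update is asymptotically biased by roughly
$(\delta_1 - 1)\,\mathbb{E}[LP]$, so baseline-shift recovery is exercised on
shift-only data and shape recovery on shift-plus-shape data, where the
joint intercept-and-slope refit recovers both.

## A worked example

```{r example, eval = FALSE}
sw <- oxrec_coefs("sweden-synthetic")

# a validation-study-sized cohort, outcomes from the model itself
coh <- sample_cohort(cohort_spec(970, seed = 1))
sim <- simulate_outcomes(coh, sw, seed = 2)

ladder <- run_ladder(sim$cohort, sw)
ladder
```

On calibrated input every stage shows CITL ≈ 0, slope ≈ 1 and E:O ≈ 1; with
an injected `baseline_shift` the simple stage shows the classic signature
of underestimated risk (positive CITL, E:O < 1) that the baseline stage
then removes.

## Known limitations

* Independent predictors and a single categorical age band understate real
  case-mix complexity; parameter recovery under correlated predictors is
  untested.
* The selective stage currently supports categorical predictors only.
* Time-to-event structure (and with it censoring-adjusted calibration or
  time-dependent discrimination) is out of scope, as is any sex-stratified
  validation, which the motivating study could not do either for sample
  size reasons.
* In-sample updating slightly flatters the post-update report; the spread
  between in-sample and split-sample performance is not quantified here.
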