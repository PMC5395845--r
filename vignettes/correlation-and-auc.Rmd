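---
title: "Predictor correlation, case-mix heterogeneity and the AUC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predictor correlation, case-mix heterogeneity and the AUC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aucmix)
```

## The model

Every population in `aucmix` consists of `n` individuals carrying two
continuous predictors $x_1, x_2$ and a binary disease outcome $y$. Risk
follows a two-predictor logistic model

$$\Pr(y = 1 \mid x) = \operatorname{expit}(\beta_0 + \beta_1 x_1 + \beta_2 x_2),$$

and discrimination is measured by the AUC — the probability that a random
case's linear predictor (LP) exceeds a random control's. Because the AUC is a
rank statistic of the LP, it is invariant to monotone transforms of the score
and, conditional on outcome status, independent of prevalence.

The object of study is the *correlation* $\rho$ between $x_1$ and $x_2$,
viewed as a dimension of case-mix alongside the predictor means and SDs. The
link runs through the spread of the LP: for jointly Gaussian predictors,

$$\operatorname{SD}(LP) = \sqrt{\beta_1^2\sigma_1^2 + \beta_2^2\sigma_2^2 +
  2\rho\,\beta_1\beta_2\,\sigma_1\sigma_2},$$

so with same-direction effects ($\beta_1\beta_2 > 0$) a more positive $\rho$
widens the LP distribution and raises the AUC, while with opposite-direction
effects the cross term changes sign and the relation inverts. The package's
correlation sweeps trace exactly this: across a sweep, the rank ordering of
`sd_lp` and of the AUC agree (Spearman correlation 1 up to Monte-Carlo
noise), which the test suite asserts.

## The two generative approaches

**Approach I — total-population specification.** `population_spec_a1()`
fixes the joint distribution of the predictors in the whole population
(means `mu`, SDs `sigma`, correlation `rho`) and the per-unit *adjusted*
odds ratios. Simulation proceeds in three seeded stages:

1. draw `n` rows from the bivariate Gaussian (Cholesky factor of the
   covariance applied to independent standard normals — exactly reproducible
   and numerically standard for a 2×2 covariance);
2. set $\beta = \log(\text{adjusted OR})$ and calibrate $\beta_0$ so that the
   *realized sample's* mean risk equals the target prevalence (monotone
   root-finding on $\beta_0$, polished by Newton steps; the achieved mean
   risk is within $10^{-10}$ of target, asserted at $10^{-8}$ in tests). The
   calibration is empirical rather than an integral over the theoretical
   distribution, so the target is met exactly in the data actually analysed;
3. draw each outcome from a Bernoulli with the individual's risk.

Realized prevalence therefore fluctuates binomially around 20%; the cohort
stores it as metadata.

**Approach II — outcome-conditional specification.**
`population_spec_a2()` instead fixes the predictor distribution *within
cases* and *within controls*. Exactly `round(n × prevalence)` cases are
drawn — a fixed case count, deliberately asymmetric to Approach I's Bernoulli
mechanism, mirroring the two standard constructions of case/control
simulation designs. Rows are shuffled with a seed-derived permutation so no
downstream code can exploit block ordering. Adjusted effects are estimated,
not fixed: they emerge from the logistic fit and shrink as the within-group
correlations grow. Closed forms accompany the simulator:

* `mixture_moments()` gives the total-population mean, SD and correlation of
  the two-component Gaussian mixture (mixture-of-variances plus
  between-group mean-shift terms);
* `unadjusted_or()` gives the single-predictor odds ratio
  $\exp((\mu_{case}-\mu_{control})/SD^2)$, exact when the within-group SDs
  are equal. When they differ that assumption is violated; the function then
  uses the control-group SD and warns rather than failing, since the
  quantity remains a useful descriptive approximation.

## Parameters and defaults

* `n = 100000` per population: large enough that the Monte-Carlo standard
  error of an AUC estimate is ≈ 0.002 (with 20,000 cases), so printed AUCs
  are stable to the second decimal. All constructors accept smaller `n` for
  fast exploration, and the unit tests use sizes from 8 to 100000 depending
  on what a check needs.
* `prevalence = 0.2` everywhere; the AUC itself is prevalence-independent,
  so this choice affects only the precision of case-side summaries.
* Bundled scenario sets: `table1_specs()` (sixteen Approach I populations
  A–P) and `table2_specs()` (nine Approach II populations A–I) span
  correlations from −0.2 to +0.4 — the range typically observed among
  non-genetic biomedical predictors — crossed with weak (1.2), moderate
  (1.5), strong (3) and protective (0.8) per-unit odds ratios, and predictor
  SDs of 1–3.
* Sweep grids: Approach I defaults to $\rho \in \{-0.4, \dots, 0.4\}$ in
  steps of 0.1; Approach II sweeps extend to ±0.95 in steps of 0.05 because
  the interesting re-inversion of the correlation–AUC relation only appears
  at very large shared correlations (as $\rho \to 1$ with equal group
  correlations, the two LP distributions separate and the AUC approaches 1).
  Both grids are arguments, not constants.

## Model fitting and evaluation choices

* `fit_logistic()` delegates the maximum-likelihood fit to iteratively
  reweighted least squares (`stats::glm`) with the relative-deviance
  convergence threshold tightened to $10^{-12}$ and up to 100 iterations.
  The returned model carries the iteration count, convergence flag and the
  largest absolute mean-score component — at the optimum the score equations
  $\overline{(y-p)} = \overline{x_j(y-p)} = 0$ hold to machine precision
  (asserted at $10^{-6}$), which also forces the mean in-sample predicted
  risk to equal the realized prevalence.
* Separation is declared when any slope exceeds 50 in absolute value or any
  fitted probability reaches a $10^{-12}$ boundary; the fit errors rather
  than returning a silently divergent model.
* AUC uses the midrank (Mann–Whitney) formula, ties counted ½. Development
  (in-sample) evaluation uses `direction = "fixed"` — an ML fit's in-sample
  concordance cannot fall below ½. External validation defaults to
  `direction = "auto"`, reporting $\max(A, 1-A)$ with an explicit
  `flipped` flag: a transported coefficient vector can point against the
  validation population's effect directions, and the flag keeps that
  orientation choice auditable instead of silently absorbed.
* Sample SDs use the $n-1$ denominator (immaterial at $n = 10^5$, declared
  for exactness of small-sample tests). Exported tables round descriptive
  statistics to 2 decimals and AUCs to 3.

## Seeding

A single master seed drives everything. `derive_seed()` folds the seed and a
list of string labels (population id, stage name, grid value) into a new
31-bit seed, so predictor draws, outcome draws and shuffles run on
independent, individually reproducible streams: changing the logic of one
stage cannot shift another's random numbers, and any single cohort of a
large experiment can be regenerated in isolation. Each population in
`develop_all()` and each grid point of a sweep is an independent fresh draw —
populations sharing parameters do not share realizations, and sweep curves
consequently carry Monte-Carlo jitter, which is why the monotonicity checks
in the test suite allow a ±0.005 per-step tolerance rather than demanding
strict inequalities.

## What the generators do and do not emulate

The simulators produce exactly bivariate-Gaussian predictors, a correctly
specified logistic outcome model (Approach I), no measurement error, no
missingness, no confounding beyond the modelled predictor correlation, and
a constant 20% prevalence. Real validation studies violate most of these:
predictors are skewed or categorical, effects can be non-linear or interact,
disease severity varies across populations, and models are often
transported with recalibration. Passing tests therefore demonstrate the
internal mechanics — that correlation moves the AUC through the spread of
the LP, and that transported discrimination depends on the match between a
frozen coefficient direction and the validation population's structure —
not that any particular real-world model will generalize. Calibration and
other performance dimensions beyond discrimination are out of scope, as are
models with more than two predictors.

## Degenerate inputs and edge behaviour

Spec validation rejects $|\rho| \ge 1$, non-positive SDs and prevalences
outside (0, 1) by naming the offending parameter (for two predictors these
checks are equivalent to positive-definiteness of the covariance). AUC and
model fitting require both outcome classes; outcome-group summaries require
at least 3 members per group for a defined correlation. Intercept
calibration always has a unique root (mean risk is strictly increasing in
$\beta_0$) and the bracket auto-expands, so it cannot fail for valid inputs.
Proportional coefficient vectors give exactly identical validation AUCs (a
rank argument), which is asserted exactly, not within tolerance.

## Problem sizes in the shipped checks

The test suite runs each headline reproduction at the full $n = 10^5$ (the
size the AUC targets are defined at), and structural/invariant checks at
$n$ between 8 and $5\times10^4$; one mixture-moment Monte-Carlo oracle uses
$10^6$ draws. The complete suite and the acceptance script each finish in
about a minute on one CPU.
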