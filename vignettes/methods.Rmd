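---
title: "Imputing a longitudinal ordinal outcome at a fixed target day: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Imputing a longitudinal ordinal outcome at a fixed target day}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Observational studies of traumatic brain injury follow patients with the
extended Glasgow Outcome Scale (GOSe), an 8-category ordinal measure of
functional recovery, at protocol visits around 2 weeks, 3 months, 6 months and
12 months post-injury. The primary endpoint is typically the GOSe at 180 days,
but assessments land anywhere in a wide protocol window and many are missed
entirely. The common fix — carrying the last observation forward (LOCF) — is
biased whenever the population is still recovering at the target day, cannot
use observations made *after* day 180, and offers no measure of uncertainty.

This package implements and compares five single-imputation strategies that
each return, per patient, a full probability distribution over the GOSe
categories at the target day:

* **LOCF** — the last observation strictly before the target day, represented
  as a degenerate point-mass distribution so that the same metric machinery
  applies.
* **MICE panel imputation** — observations are mapped to the four protocol
  windows and the resulting incomplete wide panel is completed by chained
  proportional-odds regressions; the 6-month draw frequencies across completed
  data sets are the predictive distribution.
* **Cumulative-link mixed model (CLMM)** — a cumulative-probit regression with
  a natural-spline population trend in time and per-patient
  (intercept, slope, quadratic) random effects.
* **Gaussian-process (GP) regression** — a latent-variable model in which each
  patient deviates from the population mean trajectory by a smooth Gaussian
  process.
* **Multi-state model (MSM)** — a continuous-time Markov chain on the ordinal
  state space, fitted from panel observations by maximum likelihood via the
  matrix exponential.

Throughout, the living scale has six states: GOSe 2 (vegetative state) is
merged into GOSe 3, because postal questionnaires cannot distinguish them, and
category 1 (dead) is excluded by conditioning on survival at the target day —
the outcome can only be *missing* for survivors. Observations later than 547
days (18 months) are dropped as uninformative for a 6-month endpoint.

## The synthetic cohort generator

Real data of this kind are access-controlled, so the package ships a generator
that emulates the study design and is itself a tested, first-class module.

**Latent truth.** Each patient's trajectory is a continuous-time Markov chain
on the six living states with adjacent-state (birth–death) transitions and a
piecewise-constant time effect: all intensities are multiplied by 0.3 after a
knot at day 180. This is the simplest mechanism that produces the population
feature the comparison hinges on — continued recovery over the first six
months, which makes LOCF negatively biased — while remaining exactly the model
class the MSM assumes. A `skip_frac` parameter adds two-state jumps for
testing methods under mild misspecification (default 0).

The default intensities and the initial distribution were calibrated once,
analytically via the matrix exponential, to reproduce the qualitative marginal
features of a large TBI cohort: strong category imbalance with GOSe 4 rarest
(~5% at day 180) and GOSe 7–8 most frequent (~46%), and a mean GOSe rising
from about 5.0 at two weeks to 6.0 at six months. They are fixed defaults, not
fitted quantities.

**Observation process.** Visits follow the stratum schedules (emergency room:
days 14/91/180; ward and ICU: 91/180/365) with Gaussian jitter (SD 10 days,
clamped to `[1, 547]`); each visit is independently missed with probability
0.3. The miss probability may be a function of the covariates but never of the
latent state, so missingness is *missing at random by construction* — the
generator asserts an MAR stand-in, not an estimate of any real missingness
mechanism. Under these defaults roughly 60% of retained patients have a valid
observation in the 180 ± 14-day window, giving stable three-fold
cross-validation at the default cohort size of 3000.

**Covariates.** Baseline covariates (the IMPACT set: age, GCS motor score,
pupil reactivity, hypoxia, hypotension, Marshall CT class, traumatic
subarachnoid hemorrhage, epidural hematoma, glucose, hemoglobin, plus sex and
stratum) are drawn from simple parametric marginals roughly matching a typical
TBI cohort, with realistic per-variable missingness. Age loads log-linearly on
the upward intensities (−0.15 per decade above 45 by default), giving the
covariate-using method variants a real signal to find. What the generator does
*not* emulate: interview-versus-postal measurement error, informative
missingness, correlated covariates, or calendar-time effects — so passing
tests demonstrate correctness of the machinery under the stated mechanism, not
performance on any real cohort.

**Reproducibility.** A single global seed is split deterministically per
patient (`seed_i = (seed + 48271 · i) mod 2^31 − 1`), so any patient's data
are reproducible regardless of cohort size, and the whole pipeline is
byte-identical under a fixed seed.

## Model details and numerical choices

### Multi-state model

The likelihood of panel data is the product over consecutive observation
pairs of `P(Δt)[s_i, s_j] = expm(Q Δt)` entries; first observations are
conditioned on, and single-observation patients contribute nothing. The
default transition structure is adjacent-state only: with 1–4 observations per
patient a dense 6 × 6 intensity matrix is not identifiable, and the adjacent
structure is the standard choice for an ordinal scale. Covariates enter
proportionally, `q_rs(x) = q_rs⁰ exp(β_rs z)` with `z = (age − 45)/10`; only
age is supported, reflecting the numerical-stability considerations that apply
to richer covariate sets in this model class.

Fitting is box-constrained quasi-Newton (L-BFGS-B) on the log-intensities from
the deterministic start `log(0.005/day)`, with a floor at `log q = −12` so
that unidentified transitions are driven to an effective zero without leaving
the parameter space. The default chain is time-homogeneous; a two-epoch
variant (`knot = 180`) multiplies all intensities by a fitted factor after the
knot and recovers the generator's slowdown factor well. The homogeneous
default is deliberately a *mildly misspecified* model of the default generator
— its remaining negative bias at the target day is part of what the
evaluation measures.

Prediction at the target day conditions on the nearest observation on each
side (the Markov property makes farther ones irrelevant): with brackets
`s_L` at `t_L` and `s_R` at `t_R`,
`P(state = k) ∝ P(t_L→180)[s_L, k] · P(180→t_R)[k, s_R]`. With only earlier
observations the row of the transition matrix is used directly. With only
later observations a prior at the target is needed; we use the empirical
distribution of first observed categories in the training data, evolved from
its mean observation day to the target, inverted through Bayes' rule. That
prior is an acknowledged approximation, logged in the fit object. An empty
panel yields "not applicable" rather than a population guess, which keeps the
method's coverage semantics explicit in the evaluation.

### Cumulative-link mixed model

The observed category is a thresholded latent Gaussian:
`u = f(t) + x'β + b₀ + b₁ s(t) + b₂ s(t)² + ε`, `ε ~ N(0,1)`, with `f` a
natural cubic spline (df = 4 over `[0, 547]`, interior knots at quantiles of
observation times) and `s(t) = (t − 180)/365`. The probit link is chosen so
that conditioning the latent variable on the Laplace posterior of the random
effects stays within the Gaussian family and the predictive category
probabilities are exact normal integrals. The random-effect covariance is
diagonal (SDs for intercept, slope, quadratic), which keeps the marginal
likelihood well-conditioned at panel sizes of 1–4 observations; fitting
maximizes the Laplace-approximated marginal likelihood from a documented
deterministic start (thresholds from marginal category frequencies, zero
trend, SDs 1/0.5/0.25). This is a deliberate point-estimated stand-in for a
fully Bayesian fit: it preserves the probabilistic per-patient output the
comparison needs while avoiding sampler convergence questions. The Laplace
approximation also means single-observation posteriors are approximated
Gaussians; against an exact 2-D quadrature oracle the category probabilities
agree to about 0.01–0.02, which is the accuracy level the package claims (and
tests) for this component.

### Gaussian-process regression

The latent variable decomposes as population mean plus patient-level process
plus noise: `u(t) = m(t, x) + f(t) + ε`. The total latent variance is fixed at
1 (the probit scale), split as `Var f = ρ` and `Var ε = 1 − ρ`; `f` has a
squared-exponential kernel with length-scale `ℓ` in days. Estimation is
two-stage: a cumulative-probit regression on the spline basis (plus
standardized covariates; missing values sit at the training mean) fixes the
thresholds and `m` on the unit scale, then `(ρ, ℓ)` maximize the
Laplace-approximated marginal likelihood summed over a subsample of up to 400
patients with ≥ 2 observations (single-observation patients carry no
information about `ℓ`). Prediction uses standard GP-Laplace conditioning. The
unit-variance constraint means the "infinite noise" limit is expressed as
`ρ → 0`, in which case every patient receives the population distribution
regardless of their data. The covariate-using variant is the default, as it is
the variant of this model class worth carrying into a comparison.

### Chained-equation panel imputation

Window mapping rounds each observation to the nearest nominal day (boundaries
at the midpoints 52.5 / 135.5 / 272.5 days; everything up to 547 days falls in
the 12-month window), so the "6-month" window deliberately contains
observations up to 9 months. Within a window the observation closest to the
nominal day wins, ties to the earlier. The conditional model for each window
is proportional-odds logistic with the other three windows as *numeric*
predictors — six-level factors would hit empty-cell separation at realistic
panel sizes. When a conditional fit fails anyway (near-deterministic panels
defeat the default starting values), the fit is retried from zero slopes and
marginal thresholds, and only then falls back to resampling the window's
observed marginal, with a logged counter. Defaults are M = 50 chains and 10
sweeps; neither is prescribed by the method, and they were chosen once so
that the modal imputed value is stable across seeds at desk scale. Deaths
after the target day (category 1) are excluded from the panel: the windows
model the living scale.

### Evaluation protocol

Eligible patients have a valid (living-scale) observation in 180 ± 14 days;
the in-window observation closest to the target is the ground truth (ties to
the earlier). Folds (default 3) are stratified on the observed category —
whether the original protocol stratified or relied on chance balance is not
stated, so balance is made explicit here and can be disabled. In each fold,
*all* in-window observations of the fold's patients are removed; every method
is fitted on everything else, including the test patients' out-of-window
observations; predictions are made from the window-removed records.

Metrics use the convention `bias = mean(imputed − observed)` — negative means
imputing lower than observed. The directional bias is
`P(imputed > observed) − P(imputed < observed)` under each patient's predictive
distribution, averaged like the others: within fold, then across folds, with
the standard error taken over folds. Comparisons that include LOCF are
restricted, for every method, to the patients where LOCF is applicable.
Confusion matrices are fold-averaged counts (rows imputed, columns observed)
plus a column-normalized variant conditional on the observed category. The
subgroup comparison table uses Pearson χ² *without* continuity correction for
categorical covariates — the convention that reproduces standard printed
baseline tables, which a corrected test does not — and the normal-approximation
Wilcoxon rank-sum test for continuous ones.

Point imputations are always the modal category with ties broken toward the
lower (worse) category, the conservative and deterministic convention, applied
identically across methods. Multiple imputations can be drawn post hoc from
any stored predictive distribution by inverse-transform sampling, which is why
the prediction files carry the six probability columns.

## Problem sizes and test design

The package's test suite verifies each numerical component against an
independent oracle: the matrix exponential against the 2-state closed form and
a stationary-distribution eigendecomposition; the event-driven simulator
against the matrix exponential at 20,000 paths; the bracketed MSM prediction
against 100,000 rejection-sampled bridge paths; the CLMM prediction against a
2-D quadrature; metrics against a brute-force recomputation. Parameter
recovery uses 2000 patients for the MSM (every free intensity within 15%) and
1000 for the CLMM (thresholds within 0.15 latent units). The end-to-end
comparison runs all five methods under 3-fold cross-validation on the default
3000-patient cohort and checks the qualitative findings: LOCF biased low, the
MSM's absolute bias strictly smaller, accuracy best at the most frequent
categories, and both bias measures agreeing in sign. These sizes were chosen
as the smallest at which the Monte-Carlo error of each check is comfortably
below the effect being asserted.

## Known limitations

* The Bayesian fits this package's CLMM and GP stand in for would propagate
  parameter uncertainty into the predictive distributions; the point-estimated
  versions understate predictive spread somewhat.
* The MSM's only-right-bracket prior (first-observation distribution evolved
  to the target) is a heuristic; it affects the small subset of patients whose
  first observation falls after the target day.
* The generator's MAR mechanism is a stand-in. Nothing here validates any
  method against informative missingness.
* The proportional-odds conditional models in the chained-equation method use
  numeric window scores; genuinely non-monotone dependence between windows
  would be missed.
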