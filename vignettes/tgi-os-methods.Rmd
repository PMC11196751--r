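---
title: "Linking tumor growth inhibition to overall survival: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking tumor growth inhibition to overall survival: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In solid-tumor trials, longitudinal tumor burden — the RECIST sum of longest
diameters (SLD) of target lesions, in mm — carries prognostic information
about overall survival (OS) well before OS itself matures. Tumor growth
inhibition (TGI) modeling compresses each patient's SLD trajectory into a few
kinetic parameters, which then feed survival models. The classical pathway is
indication-specific: a parametric survival regression trained per tumor type.
That breaks down when a trial spans tumor types with little historical data,
which motivates the second pathway implemented here: a tumor-type-agnostic
("pan-indication") machine-learning survival model that never sees the tumor
type as a feature.

`tgisurv` implements both pathways plus everything needed to exercise them
without access to restricted trial data: a seeded synthetic-trial generator,
the TGI fitting machinery, the two OS models, bootstrap prediction bands,
SHAP explanations, and the stratified evaluation layer.

## The TGI model

SLD is modeled biexponentially,

$$\mathrm{SLD}(t) = \mathrm{SLD}_0\left(e^{-K_S t} + e^{K_G t} - 1\right),$$

with shrinkage rate $K_S$ and regrowth rate $K_G$, both in 1/day (the time
unit is days throughout; sources in this literature vary between per-day and
per-week rates, so the unit is stated explicitly everywhere). The curve's
minimizer gives the time to tumor growth,

$$\mathrm{TTG} = \max\!\left(0,\; \frac{\log(K_S/K_G)}{K_S + K_G}\right),$$

clamped at zero when $K_S \le K_G$: a trajectory that never shrinks "regrows"
immediately, and 0 is the only value consistent with that reading. A patient
is *TGI-evaluable* when they have a baseline (day 0) measurement and at least
one post-baseline measurement; only evaluable patients enter the TGI fit,
while the ML pathway keeps non-evaluable patients with missing TGI features.

### Estimation

The reference methodology estimates the model as a nonlinear mixed-effects
model in specialized software. This package instead uses a self-contained
empirical-Bayes alternation:

1. **Individual MAP fits.** For each patient, minimize the residual sum of
   squares on $(\log \mathrm{SLD}_0, \log K_S, \log K_G)$ — the log
   parameterization enforces positivity, and $\log K_G$ is bounded below at
   $\log(10^{-6})$/day — plus a quadratic penalty toward the population
   means weighted by $\sigma^2/\omega^2_p$. Three jittered starts guard
   against local minima in the first pass (best SSE wins, ties to the first
   start); later passes warm-start from the previous estimate.
2. **Population updates.** Group means of the individual log-parameters;
   inter-individual variances $\omega^2$; pooled residual SD $\sigma$.

Two refinements proved necessary:

* **Initialization from unpenalized fits.** Starting the population at
  guessed values and iterating MAP fits can freeze weakly identified
  parameters at the guess. Stage 0 therefore fits every patient with at
  least 3 measurements by plain least squares and initializes the
  population from those estimates.
* **Posterior-variance-corrected $\omega^2$.** The naive moment update
  ($\omega^2$ = variance of the MAP point estimates) is biased low because
  MAP estimates are shrunken; for $K_S$ — identified mostly by the first
  follow-up visit when shrinkage is fast relative to the visit interval —
  it collapses $\omega^2$ to zero and the population mean stops moving. The
  update used here adds each patient's Laplace posterior variance
  ($2\sigma^2 H^{-1}$ from the penalized objective's Hessian, capped at the
  prior variance) to the between-patient variance of the point estimates.
  This is the standard MAP-EM correction, and with it the package's own
  recovery criteria pass comfortably.

Outer-loop convergence is declared at a relative parameter change below
1e-4, capped at 50 iterations; individual optimizations use L-BFGS-B with a
tight factor (`factr = 1e4`). Goodness of fit is summarized per patient
(R², residual SD, observed-vs-predicted pairs) and pooled.

## The parametric OS pathway

For TGI-evaluable patients (complete-case covariates), the pathway is:
Kaplan–Meier curves (own product-limit implementation, validated against
`survival::survfit`), univariate Cox screening (via `survival::coxph`,
Breslow ties; constant features are flagged degenerate with p = 1), then an
accelerated-failure-time regression fit by maximum likelihood
(`survival::survreg`) for each of the exponential, Weibull, lognormal and
log-logistic families, keeping the lowest AIC (ties broken in that order).
Backward stepwise elimination then repeatedly drops the covariate with the
largest likelihood-ratio p-value at or above `alpha`, refitting each round.
The likelihood-ratio test was chosen over Wald for its better small-sample
behavior and because it makes the retained set independent of column order.
`alpha` defaults to 0.01; the source methodology quotes both 0.01 (for
elimination) and 0.05 (for the covariates it lists as significant), so the
threshold is deliberately configurable rather than silently reconciled.

Per-patient survival curves come from the fitted family's closed-form
survival function at the AFT linear predictor.

## The ML OS pathway

Features are exactly `KS`, `KG`, `TTG` plus eight baseline covariates (ECOG,
hemoglobin, albumin, neutrophil-to-lymphocyte ratio, liver metastasis,
number of tumor sites, neutrophil count, years since diagnosis). Tumor type,
sex and race are never columns. Missing TGI features (non-evaluable
patients) pass through to the tree learner's learned default directions —
no imputation.

The estimator is a from-scratch gradient-boosted tree ensemble (exact greedy
splits, second-order Newton leaf weights, L2 penalty, native missing-value
routing; no subsampling, so training is deterministic) under a normal AFT
loss on log-days (scale fixed at 1.0, the conventional default), followed by
a survival embedding: per-patient curves are the Kaplan–Meier estimate over
the patient's `k = 30` nearest training neighbors in terminal-leaf
co-occurrence space (fraction of trees sharing a leaf; ties broken by
training-row order). This "neighbor-KM" variant was chosen over stacked
parametric alternatives because it is implementable from primitives and
yields calibrated step curves. Default hyperparameters: depth 3, learning
rate 0.1, 200 rounds, `lambda = 1`, `min_child_weight = 1`.

Predictions live on a fixed grid of 0 to 2000 days in steps of 5 (401
points). Curves are clipped non-increasing as a safety net; neighbor-KM
curves are already monotone, and the clipping magnitude is reported.

Bootstrap prediction bands refit the entire model on each of `B` resamples
(the reference analysis used `B = 1000`; the test suite scales to 200),
predict the subgroup's per-patient curves, pool by the mean, and take
pointwise 2.5/50/97.5 percentiles. Pooling by mean curve (rather than a KM
of predicted event times) was an open choice; the mean is the standard
reading of "pooled predicted survival". Model-level refitting (rather than
resampling predictions) was likewise chosen because replicated *model*
predictions are what the band is meant to describe.

## Explanations

SHAP attributions use the exact path-dependent TreeSHAP recursion on the
boosting stage's margin, negated so that positive attributions mean higher
predicted hazard; the neighbor-KM stage is not attributed (TreeSHAP operates
on trees, and the margin is the model's risk score). Local accuracy —
base value plus attribution row sum equals the risk score — holds to
machine precision and is verified against brute-force Shapley enumeration
on small models in the test suite. Rankings use mean absolute attribution,
ties broken alphabetically.

## The synthetic trial

The generator states a world matching the structure the models assume:

* Four default groups sized 313 / 224 / 28 / 20 (NSCLC, MTC, other
  fusion-positive, other altered), with MTC given the slowest regrowth
  (median $K_G$ 0.0015/day vs 0.004 for NSCLC) so tumor-type contrasts in
  the TGI metrics and OS have the qualitatively expected direction.
* Individual $(\mathrm{SLD}_0, K_S, K_G)$ drawn log-normally; default IIV
  variances 0.25 (rates) and 0.1 (baseline size) on the log scale; additive
  normal residual with SD 5 mm on observed SLD, clamped at 0 mm (a negative
  diameter sum is physically impossible; clamping rather than re-drawing
  keeps the noise-free case exact).
* Visits every ~52 days, 8 visits over one year; monotone dropout (a
  patient who misses a visit misses all later ones), 5% per visit.
* Survival from a lognormal or Weibull AFT whose linear predictor combines
  the *true* $\log K_G$ with baseline covariates; exponential random
  censoring plus administrative censoring at day 1200.
* Baseline covariates are independent draws from simple parametric families
  with plausible oncology-trial marginals (ECOG 0/1/2 at 40/45/15%,
  hemoglobin ~N(12.5, 1.5) g/dL, albumin ~N(4.0, 0.45) g/dL, NLR
  log-normal around 3, 25% liver metastasis, 1 + Poisson(1.5) tumor sites,
  neutrophils log-normal around 4.5e9/L, years-since-diagnosis exponential
  with mean 2, 30% Asian, balanced sex). The source trial publishes no
  covariate distributions, so these are plausibility choices, not fidelity
  claims.
* Trajectory/covariate randomness and survival randomness use separate
  seeds so either can be held fixed.

What a green test does **not** establish: the generator has independent
covariates, a single shared visit schedule, noise-free baseline values and a
correctly specified AFT link — real trial data have correlated covariates,
irregular visits, measurement artifacts and unknown links. Green recovery
tests certify the estimation machinery, not clinical transportability.

## Numerical choices and degenerate inputs

* TTG clamps at 0; `biexp_sld` rejects non-positive parameters.
* The TGI objective returns a large finite value when the regrowth
  exponential overflows, keeping L-BFGS-B on finite ground; $\log K_G$ is
  additionally bounded above at $\log(0.2)$/day.
* Individual fits with fewer than 3 points are rejected unless a population
  prior is supplied; a $K_G$ estimate at its lower bound is flagged
  `at_boundary` with `converged` still honest.
* Groups with fewer than 2 evaluable patients contribute no variance
  information; their $\omega^2$ is reported from the pooled update only.
* Backward elimination with `alpha = 1` is a guaranteed no-op; an
  intercept-only model is a legal outcome.
* Quartile stratification assigns ties to the lower group; group sizes
  differ by at most 1 for distinct values.
* Pairwise tumor-type comparisons use two-sided Wilcoxon rank-sum tests
  with Holm adjustment within each metric — the source figures do not name
  a test family, and the rank-sum test is robust to the skewed log-metric
  distributions involved; whether the original p-values were
  multiplicity-adjusted is unstated, so both raw and adjusted values are
  reported.
* Band coverage is evaluated only up to each subgroup's last observed event
  time, where the KM curve is defined.

## Known limitations

* The empirical-Bayes alternation is not a marginal-likelihood NLME fit
  (no FOCE/SAEM); covariate effects on TGI parameters are out of scope.
* The boosted ensemble has no hyperparameter search; defaults are stated,
  not tuned.
* The C-index convention anchors comparable pairs at observed events
  (Harrell); tied event times are not comparable pairs.
* Lesion-level modeling, PK, time-varying covariates and frailty terms are
  all out of scope.

## A worked run

```{r example}
library(tgisurv)
co <- simulate_cohort(default_cohort_config(seed = 1),
                      surv_gen_config(seed = 2))
fit <- fit_tgi_population(co$longitudinal, co$baseline)
fm <- build_feature_matrix(fit$individuals, co$baseline)
model <- train_ml_survival(fm, co$survival)
rank_features(compute_attributions(model, fm))
```
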