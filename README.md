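# tgisurv

Tumor-dynamics-to-survival modeling for multi-tumor-type oncology trials.

Longitudinal tumor burden — the RECIST sum of longest diameters (SLD, mm) —
is compressed per patient into tumor growth inhibition (TGI) kinetics by the
biexponential model

    SLD(t) = SLD0 * ( exp(-KS * t) + exp(KG * t) - 1 ),

with shrinkage rate `KS` and regrowth rate `KG` (1/day) and time to tumor
regrowth `TTG = max(0, log(KS/KG) / (KS + KG))` (days). Those metrics then
predict overall survival two ways:

* **Parametric pathway** — Kaplan–Meier estimation, univariate Cox
  screening, accelerated-failure-time regression with AIC family selection
  (exponential / Weibull / lognormal / log-logistic) and backward
  likelihood-ratio elimination (default `alpha = 0.01`).
* **Pan-indication ML pathway** — a gradient-boosted tree ensemble under a
  normal AFT loss (from-scratch C++ core with native missing-value
  routing), per-patient survival curves via Kaplan–Meier over terminal-leaf
  nearest neighbors, predictions on a fixed 0–2000 day grid in 5-day steps
  (401 points), bootstrap 95% prediction bands, and exact path-dependent
  TreeSHAP attributions. Tumor type is never a feature.

A seeded synthetic-trial generator (biexponential trajectories with
log-normal inter-individual variability, additive residual noise, monotone
dropout, AFT survival driven by true `log(KG)` and baseline covariates)
makes the whole pipeline testable without restricted trial data. It is
first-class, tested code — not a fixture.

Audience: pharmacometricians and biostatisticians prototyping TGI–OS
analyses, and anyone needing a self-contained, dependency-light reference
implementation of the parametric-vs-ML comparison.

## Worked example

```r
library(tgisurv)

co  <- simulate_cohort(default_cohort_config(seed = 1), surv_gen_config(seed = 2))
fit <- fit_tgi_population(co$longitudinal, co$baseline)
round(fit$population$mu, 2)
#>           MTC NSCLC OTHER_ALT OTHER_FUS
#> logSLD0  3.82  4.12      4.06      4.04
#> logKS   -3.91 -3.54     -3.46     -3.35
#> logKG   -6.47 -5.56     -5.21     -5.22

fm    <- build_feature_matrix(fit$individuals, co$baseline)
model <- train_ml_survival(fm, co$survival)
risk  <- predict_risk(model, fm)
concordance_index(risk, co$survival)
#> [1] 0.938042

head(rank_features(compute_attributions(model, fm)), 4)
#>   feature mean_abs_attribution
#> 1      KG            0.5222432
#> 2    ECOG            0.2092322
#> 3    ALBU            0.1709566
#> 4     TTG            0.1692236
```

Reading the output: the recovered group means show MTC with the slowest
regrowth (`logKG` −6.5, i.e. KG ≈ 0.0015/day) and the small
fusion/alteration groups the fastest, matching the generating world; the
trained model ranks `KG` as the dominant hazard driver by mean absolute
SHAP attribution, with ECOG, albumin and TTG next — echoing the expected
KG > TTG > KS ordering of the TGI metrics. The training-set concordance of
≈0.94 is in-sample (the generator encodes a strong `log(KG)` effect); the
held-out figure the test suite checks on a comparable world is ≈0.64.

The full orchestration (`simulate → fit-tgi → both OS models → explain →
evaluate`, with CSV/JSON/PNG artifacts and an md5-hashed run manifest):

```r
run_pipeline(read_run_config("config.json"))
```

or from the shell:

```sh
Rscript -e 'tgisurv::tgisurv_cli()' run-all --config config.json --out results --seed 1
```

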