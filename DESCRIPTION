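Package: tgisurv
Title: Tumor Growth Inhibition Modeling and Pan-Indication Survival Prediction
Version: 0.1.0
Authors@R:
    person("ARROW", "Modeling Group", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Links longitudinal tumor size dynamics to overall survival in
    multi-tumor-type oncology trials. Fits a biexponential tumor growth
    inhibition (TGI) model to sum-of-longest-diameters trajectories via an
    empirical-Bayes alternating scheme, derives the shrinkage rate (KS),
    regrowth rate (KG) and time-to-tumor-growth (TTG) metrics, and predicts
    overall survival two ways: a parametric accelerated-failure-time
    regression with Cox univariate screening and backward elimination, and a
    tumor-type-agnostic gradient-boosted tree survival model with
    terminal-leaf neighbor Kaplan-Meier curves, bootstrap 95% prediction
    intervals and exact tree-path SHAP attributions. Includes a seeded
    synthetic-trial generator so every stage is testable without access to
    restricted trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    survival,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
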