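ML_FEATURES <- c("KS", "KG", "TTG", "ECOG", "HGB", "ALBU", "NLR",
                 "liver_met", "n_tumor_sites", "NEU", "YSD")

#' Prediction time grid: 0 to 2000 days in steps of 5
#'
#' @return numeric vector of 401 days.
#' @export
time_grid <- function() seq(0, 2000, by = 5)

#' Hyperparameters for the gradient-boosted survival model
#'
#' @param max_depth tree depth (default 3)
#' @param eta learning rate (default 0.1)
#' @param nrounds boosting rounds (default 200)
#' @param k neighbor count for the terminal-leaf Kaplan-Meier curves
#'   (default 30)
#' @param lambda L2 leaf penalty (default 1)
#' @param min_child_weight minimum child hessian sum (default 1)
#' @param sigma scale of the normal AFT loss on log-days (default 1)
#' @return named list of class `ml_hyperparams`.
#' @export
ml_hyperparams <- function(max_depth = 3, eta = 0.1, nrounds = 200, k = 30,
                           lambda = 1, min_child_weight = 1, sigma = 1) {
  stopifnot(max_depth >= 1, eta > 0, nrounds >= 1, k >= 1, lambda >= 0,
            min_child_weight >= 0, sigma > 0)
  structure(list(max_depth = as.integer(max_depth), eta = eta,
                 nrounds = as.integer(nrounds), k = as.integer(k),
                 lambda = lambda, min_child_weight = min_child_weight,
                 sigma = sigma), class = "ml_hyperparams")
}

#' Assemble the tumor-type-agnostic feature matrix
#'
#' Left-joins individual TGI metrics onto the baseline covariates, producing
#' exactly the 11 model features: KS, KG, TTG plus the 8 baseline covariates
#' ECOG, HGB, ALBU, NLR, liver metastasis, number of tumor sites, NEU and
#' years since diagnosis. Tumor type (and sex/race) are never columns:
#' the model is pan-indication by construction. TGI non-evaluable patients
#' keep missing KS/KG/TTG — the tree learner routes missing values natively,
#' so no imputation is applied.
#'
#' @param tgi data frame with `patient_id`, `ks_per_day`, `kg_per_day`,
#'   `ttg_days` (e.g. `fit_tgi_population()$individuals`); may cover only a
#'   subset of patients
#' @param baseline data frame with `patient_id`, `ecog`, `hgb`, `albu`,
#'   `nlr`, `liver_met`, `n_tumor_sites`, `neu`, `ysd`
#' @return data frame with rownames = patient ids and exactly the 11 feature
#'   columns, in fixed order.
#' @export
build_feature_matrix <- function(tgi, baseline) {
  if (anyDuplicated(baseline$patient_id)) stop("duplicate patient ids in baseline")
  if (!is.null(tgi) && anyDuplicated(tgi$patient_id))
    stop("duplicate patient ids in tgi table")
  idx <- if (is.null(tgi) || nrow(tgi) == 0) rep(NA_integer_, nrow(baseline))
         else match(as.character(baseline$patient_id), as.character(tgi$patient_id))
  pick <- function(col) if (all(is.na(idx))) rep(NA_real_, nrow(baseline)) else tgi[[col]][idx]
  out <- data.frame(
    KS = pick("ks_per_day"),
    KG = pick("kg_per_day"),
    TTG = pick("ttg_days"),
    ECOG = as.numeric(baseline$ecog),
    HGB = baseline$hgb,
    ALBU = baseline$albu,
    NLR = baseline$nlr,
    liver_met = as.numeric(baseline$liver_met),
    n_tumor_sites = as.numeric(baseline$n_tumor_sites),
    NEU = baseline$neu,
    YSD = baseline$ysd,
    row.names = as.character(baseline$patient_id))
  out[ML_FEATURES]
}

check_feature_columns <- function(model, features) {
  diff1 <- setdiff(model$feature_names, names(features))
  diff2 <- setdiff(names(features), model$feature_names)
  if (length(diff1) || length(diff2))
    stop("feature column mismatch; missing: [",
         paste(diff1, collapse = ", "), "], unexpected: [",
         paste(diff2, collapse = ", "), "]")
}

#' Train the gradient-boosted survival model with leaf-neighbor embeddings
#'
#' Two-stage estimator in the style of survival-embedding gradient boosting:
#' (1) a gradient-boosted tree ensemble is fit to the right-censored log
#' survival times under a normal accelerated-failure-time loss (missing
#' feature values handled by learned default directions); (2) per-patient
#' survival curves are obtained by a Kaplan-Meier estimate over each
#' patient's `k` nearest training neighbors in terminal-leaf co-occurrence
#' space (fraction of trees sharing a leaf). Training is deterministic given
#' the data (exact greedy splits, no subsampling).
#'
#' @param features feature data frame from [build_feature_matrix()]
#' @param survival data frame with `time_days`, `event`, rows aligned with
#'   `features`
#' @param hyper an [ml_hyperparams()]
#' @param grid prediction time grid (default [time_grid()])
#' @return list of class `ml_survival_model`.
#' @export
train_ml_survival <- function(features, survival, hyper = ml_hyperparams(),
                              grid = time_grid()) {
  stopifnot(inherits(hyper, "ml_hyperparams"),
            nrow(features) == nrow(survival))
  if (nrow(features) < 20) stop("need at least 20 patients")
  if (sum(survival$event) == 0) stop("no events in the training data")
  X <- as.matrix(features)
  base_score <- mean(log(survival$time_days))
  booster <- .aft_boost_fit(X, survival$time_days, as.integer(survival$event),
                            hyper$nrounds, hyper$eta, hyper$max_depth,
                            hyper$lambda, hyper$min_child_weight, hyper$sigma,
                            base_score)
  leaf_train <- .boost_leaf(booster$trees, X)
  structure(list(booster = booster, hyper = hyper,
                 feature_names = colnames(X), grid = grid,
                 leaf_train = leaf_train,
                 train_time = survival$time_days,
                 train_event = as.integer(survival$event)),
            class = "ml_survival_model")
}

#' Predicted risk score (negated AFT margin)
#'
#' Higher values mean shorter predicted survival. Used for concordance and as
#' the SHAP target scale.
#'
#' @param model an `ml_survival_model`
#' @param features feature data frame with the training columns
#' @return numeric vector of risk scores.
#' @export
predict_risk <- function(model, features) {
  stopifnot(inherits(model, "ml_survival_model"))
  check_feature_columns(model, features)
  -as.numeric(.boost_predict(model$booster$trees, model$booster$base_score,
                             as.matrix(features[model$feature_names])))
}

#' Predict per-patient survival curves on the model grid
#'
#' For each query patient, the `k` training patients with the highest
#' terminal-leaf co-occurrence similarity (ties broken by training-row order)
#' define a neighborhood; the neighborhood's Kaplan-Meier curve, evaluated on
#' the grid, is the patient's predicted survival. Curves are clipped to be
#' non-increasing (the clipping magnitude is returned as an attribute; KM
#' curves are already monotone so it is normally 0).
#'
#' @param model an `ml_survival_model`
#' @param features feature data frame with the training columns
#' @return matrix `nrow(features)` x `length(grid)` of survival
#'   probabilities, with attribute `clip_magnitude`.
#' @export
predict_curves <- function(model, features) {
  stopifnot(inherits(model, "ml_survival_model"))
  check_feature_columns(model, features)
  X <- as.matrix(features[model$feature_names])
  leaf_q <- .boost_leaf(model$booster$trees, X)
  sim <- .leaf_similarity(model$leaf_train, leaf_q)
  k <- min(model$hyper$k, nrow(model$leaf_train))
  grid <- model$grid
  out <- matrix(NA_real_, nrow(X), length(grid))
  for (i in seq_len(nrow(X))) {
    nb <- order(-sim[i, ], seq_len(ncol(sim)))[seq_len(k)]
    km <- km_estimate(model$train_time[nb], model$train_event[nb])
    out[i, ] <- km_survival_at(km, grid)
  }
  raw <- out
  for (i in seq_len(nrow(out))) out[i, ] <- cummin(out[i, ])
  attr(out, "clip_magnitude") <- max(abs(out - raw))
  dimnames(out) <- list(rownames(features), grid)
  out
}

#' Bootstrap 95% prediction band for a subgroup's pooled survival
#'
#' For each of `B` bootstrap replicates, the training patients are resampled
#' with replacement, the full model is refit, the subgroup's per-patient
#' curves are predicted and pooled by the mean; the band is the pointwise
#' 2.5/50/97.5 percentile across replicates.
#'
#' @param features,survival training data (rows aligned)
#' @param subgroup logical or integer index selecting the subgroup rows whose
#'   pooled curve is predicted
#' @param B number of bootstrap replicates (>= 2; the reference analysis used
#'   1000)
#' @param hyper an [ml_hyperparams()]
#' @param grid prediction grid
#' @param seed integer seed
#' @return list of class `prediction_band` with `grid`, `lower`, `median`,
#'   `upper`, `n_bootstrap`.
#' @export
bootstrap_prediction_band <- function(features, survival, subgroup, B = 1000,
                                      hyper = ml_hyperparams(),
                                      grid = time_grid(), seed = 1L) {
  if (B < 2) stop("B must be >= 2")
  rows <- seq_len(nrow(features))
  sub <- rows[subgroup]
  if (length(sub) == 0) stop("subgroup is empty")
  sub_features <- features[sub, , drop = FALSE]
  set.seed(seed)
  curves <- matrix(NA_real_, B, length(grid))
  for (b in seq_len(B)) {
    idx <- sample(rows, replace = TRUE)
    m <- train_ml_survival(features[idx, , drop = FALSE],
                           survival[idx, , drop = FALSE], hyper, grid)
    pred <- predict_curves(m, sub_features)
    curves[b, ] <- colMeans(pred)
  }
  qs <- apply(curves, 2, quantile, probs = c(0.025, 0.5, 0.975), names = FALSE)
  structure(list(grid = grid, lower = qs[1, ], median = qs[2, ],
                 upper = qs[3, ], n_bootstrap = B), class = "prediction_band")
}
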