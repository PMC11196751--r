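#' Exact tree-path SHAP attributions for the boosted survival model
#'
#' Path-dependent TreeSHAP on the boosting stage's margin, reported on the
#' risk scale (negated AFT location), so a positive attribution means the
#' feature pushes the prediction toward higher hazard / shorter survival.
#' Local accuracy holds exactly: for every patient,
#' `base_value + sum(values[i, ])` equals the model's risk score.
#'
#' @param model an `ml_survival_model`
#' @param features feature data frame with the training columns
#' @return list of class `attribution_matrix` with `values` (patients x 11
#'   features, risk scale), `base_value` (expected risk under the training
#'   cover weighting), and `features` (the feature values, for plotting).
#' @export
compute_attributions <- function(model, features) {
  stopifnot(inherits(model, "ml_survival_model"))
  check_feature_columns(model, features)
  X <- as.matrix(features[model$feature_names])
  raw <- .tree_shap(model$booster$trees, model$booster$base_score, X)
  p <- length(model$feature_names)
  values <- -raw[, seq_len(p), drop = FALSE]   # margin -> risk scale
  colnames(values) <- model$feature_names
  rownames(values) <- rownames(features)
  structure(list(values = values, base_value = -raw[1, p + 1],
                 features = features[model$feature_names]),
            class = "attribution_matrix")
}

#' Rank features by mean absolute SHAP attribution
#'
#' @param attr an `attribution_matrix`
#' @param subgroup optional logical/integer selector of patients (default:
#'   all); must be non-empty
#' @return data frame with `feature` and `mean_abs_attribution`, descending;
#'   ties broken alphabetically.
#' @export
rank_features <- function(attr, subgroup = NULL) {
  stopifnot(inherits(attr, "attribution_matrix"))
  v <- attr$values
  if (!is.null(subgroup)) v <- v[subgroup, , drop = FALSE]
  if (nrow(v) == 0) stop("subgroup is empty")
  score <- colMeans(abs(v))
  o <- order(-score, colnames(v))
  data.frame(feature = colnames(v)[o], mean_abs_attribution = unname(score[o]))
}

#' SHAP beeswarm-style summary plot
#'
#' One horizontal band per feature (ordered by decreasing influence, top
#' first), points at the attribution values, colored by the feature value
#' (red high, blue low within the subgroup); vertical jitter is seeded so the
#' layout is deterministic.
#'
#' @param attr an `attribution_matrix`
#' @param path output PNG path
#' @param subgroup optional patient selector
#' @param max_features number of features shown (default all)
#' @param seed jitter seed
#' @return invisibly, `path`.
#' @export
shap_summary_plot <- function(attr, path, subgroup = NULL,
                              max_features = ncol(attr$values), seed = 1L) {
  stopifnot(inherits(attr, "attribution_matrix"))
  rk <- rank_features(attr, subgroup)
  feats <- head(rk$feature, max_features)
  v <- attr$values
  fx <- attr$features
  if (!is.null(subgroup)) {
    v <- v[subgroup, , drop = FALSE]
    fx <- fx[subgroup, , drop = FALSE]
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  grDevices::png(path, width = 900, height = 150 + 60 * length(feats), res = 110)
  on.exit(grDevices::dev.off(), add = TRUE)
  xl <- range(v[, feats], 0, na.rm = TRUE)
  graphics::plot(NA, xlim = xl, ylim = c(0.5, length(feats) + 0.5),
                 yaxt = "n", xlab = "SHAP value (risk scale)", ylab = "",
                 main = "SHAP summary")
  graphics::axis(2, at = rev(seq_along(feats)), labels = feats, las = 2,
                 cex.axis = 0.8)
  graphics::abline(v = 0, col = "grey60")
  ramp <- grDevices::colorRamp(c("#2166ac", "#b2182b"))
  for (j in seq_along(feats)) {
    f <- feats[j]
    x <- v[, f]
    fv <- fx[[f]]
    rk_f <- rank(fv, na.last = "keep", ties.method = "average")
    u <- (rk_f - 1) / max(sum(!is.na(fv)) - 1, 1)
    col <- rep("grey50", length(x))
    ok <- !is.na(u)
    col[ok] <- grDevices::rgb(ramp(u[ok]), maxColorValue = 255)
    y <- (length(feats) - j + 1) + runif(length(x), -0.25, 0.25)
    graphics::points(x, y, col = col, pch = 16, cex = 0.5)
  }
  invisible(path)
}
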