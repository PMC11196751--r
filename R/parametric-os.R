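#' Kaplan-Meier product-limit estimator
#'
#' @param times event/censoring times (> 0)
#' @param events event indicators, 1 = death observed, 0 = censored
#' @return list of class `km_curve` with `event_times` (distinct times with at
#'   least one event, ascending), `survival` (product-limit value just after
#'   each event time), `at_risk`, `n_events`. Censored-only input gives a
#'   flat curve at 1 (empty `event_times`).
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0) stop("empty input")
  stopifnot(length(times) == length(events), all(times > 0),
            all(events %in% c(0, 1)))
  o <- order(times)
  times <- times[o]; events <- as.integer(events[o])
  et <- sort(unique(times[events == 1]))
  n <- length(times)
  at_risk <- integer(length(et)); n_events <- integer(length(et))
  surv <- numeric(length(et))
  s <- 1
  for (k in seq_along(et)) {
    at_risk[k] <- sum(times >= et[k])
    n_events[k] <- sum(times == et[k] & events == 1)
    # single-ratio form keeps exact binary fractions (e.g. 2/3 then 1/3)
    s <- s * ((at_risk[k] - n_events[k]) / at_risk[k])
    surv[k] <- s
  }
  structure(list(event_times = et, survival = surv, at_risk = at_risk,
                 n_events = n_events, n = n), class = "km_curve")
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' @param curve a `km_curve`
#' @param t times (>= 0); the step function is right-continuous
#' @return survival probabilities.
#' @export
km_survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"))
  c(1, curve$survival)[findInterval(t, curve$event_times) + 1]
}

#' Univariate Cox screening of candidate covariates
#'
#' One single-covariate proportional-hazards fit per feature column (Breslow
#' tie handling), reporting the hazard ratio and Wald p-value. Rows with a
#' missing value in the screened column are dropped for that fit, with the
#' count used reported. A constant column cannot be fit and is flagged
#' degenerate with p = 1 by convention.
#'
#' @param features data frame of numeric/binary candidate covariates
#' @param survival data frame with `time_days` and `event` (rows aligned with
#'   `features`)
#' @return data frame with `covariate`, `hazard_ratio`, `p_value`, `n`,
#'   `degenerate`.
#' @export
cox_univariate_screen <- function(features, survival) {
  stopifnot(nrow(features) == nrow(survival))
  res <- lapply(names(features), function(nm) {
    x <- features[[nm]]
    keep <- !is.na(x)
    xs <- x[keep]
    if (length(unique(xs)) < 2) {
      return(data.frame(covariate = nm, hazard_ratio = NA_real_, p_value = 1,
                        n = sum(keep), degenerate = TRUE))
    }
    d <- data.frame(time = survival$time_days[keep],
                    event = survival$event[keep], x = xs)
    fit <- survival::coxph(survival::Surv(time, event) ~ x, data = d,
                           ties = "breslow")
    sm <- summary(fit)
    data.frame(covariate = nm, hazard_ratio = unname(exp(coef(fit))),
               p_value = unname(sm$coefficients[1, "Pr(>|z|)"]),
               n = sum(keep), degenerate = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

aft_families <- c("exponential", "weibull", "lognormal", "loglogistic")

fit_one_family <- function(family, features, survival) {
  d <- cbind(data.frame(.time = survival$time_days, .event = survival$event),
             features)
  rhs <- if (ncol(features) > 0) paste(names(features), collapse = " + ") else "1"
  fml <- as.formula(paste("survival::Surv(.time, .event) ~", rhs))
  fit <- survival::survreg(fml, data = d, dist = family)
  if (any(!is.finite(coef(fit)))) stop("non-finite coefficients")
  ll <- fit$loglik[2]
  k <- length(coef(fit)) + as.integer(family != "exponential")
  list(fit = fit, family = family, log_likelihood = ll, aic = 2 * k - 2 * ll,
       scale = fit$scale, coefficients = coef(fit),
       covariates = names(features), n = nrow(d),
       vcov = vcov(fit))
}

#' Fit a parametric accelerated-failure-time survival regression
#'
#' Each requested family is fit by maximum likelihood with right censoring;
#' the family with the lowest AIC is returned (ties broken by the order
#' exponential, weibull, lognormal, loglogistic). A family that fails to
#' converge is skipped with a warning; if all fail, an error is raised.
#'
#' @param features complete-case data frame of covariates (may have 0 columns
#'   for an intercept-only model)
#' @param survival data frame with `time_days`, `event`, rows aligned
#' @param families subset of `c("exponential","weibull","lognormal",
#'   "loglogistic")`
#' @return list of class `parametric_os_model` with the winning `family`,
#'   `coefficients`, `scale`, `log_likelihood`, `aic`, `covariates`, the
#'   per-family AIC table, and the underlying `survreg` fit.
#' @export
fit_parametric_survival <- function(features, survival,
                                    families = aft_families) {
  families <- match.arg(families, aft_families, several.ok = TRUE)
  stopifnot(nrow(features) == nrow(survival) || ncol(features) == 0)
  if (ncol(features) > 0 && any(!complete.cases(features)))
    stop("features must be complete-case for the parametric path")
  fits <- list()
  for (fam in families) {
    f <- tryCatch(fit_one_family(fam, features, survival),
                  error = function(e) {
                    warning("family '", fam, "' failed: ", conditionMessage(e))
                    NULL
                  })
    if (!is.null(f)) fits[[fam]] <- f
  }
  if (length(fits) == 0) stop("all requested families failed to fit")
  aics <- vapply(fits, `[[`, numeric(1), "aic")
  best <- fits[[which.min(aics)]]  # which.min keeps the listed order on ties
  best$aic_table <- data.frame(family = names(aics), aic = unname(aics))
  class(best) <- "parametric_os_model"
  best
}

#' Backward stepwise elimination for the parametric OS model
#'
#' Starting from the full model (family chosen by AIC among `families`, then
#' held fixed), repeatedly drops the covariate with the largest
#' likelihood-ratio p-value at or above `alpha`, refitting each round, until
#' every retained covariate has p < `alpha`. May return an intercept-only
#' model. The retained set does not depend on the input column order.
#'
#' @param features complete-case covariate data frame
#' @param survival survival data frame (`time_days`, `event`)
#' @param families candidate families for the initial selection
#' @param alpha retention threshold on the likelihood-ratio p-value
#'   (default 0.01)
#' @return a `parametric_os_model` with extra elements `alpha`,
#'   `elimination_trace` (covariate dropped and its p-value per round) and
#'   `p_values` (LRT p-values of the retained covariates).
#' @export
backward_eliminate <- function(features, survival, families = aft_families,
                               alpha = 0.01) {
  full <- fit_parametric_survival(features, survival, families)
  fam <- full$family
  current <- names(features)
  trace <- list()
  fit <- fit_one_family(fam, features[current], survival)
  repeat {
    if (length(current) == 0) break
    pvals <- vapply(sort(current), function(v) {
      reduced <- fit_one_family(fam, features[setdiff(current, v)], survival)
      lr <- 2 * (fit$log_likelihood - reduced$log_likelihood)
      pchisq(max(lr, 0), df = 1, lower.tail = FALSE)
    }, numeric(1))
    worst <- names(pvals)[which.max(pvals)]
    if (alpha >= 1 || pvals[worst] < alpha) break  # alpha = 1: degenerate no-op
    trace[[length(trace) + 1]] <- data.frame(dropped = worst,
                                             p_value = unname(pvals[worst]))
    current <- setdiff(current, worst)
    fit <- fit_one_family(fam, features[current], survival)
  }
  out <- fit
  out$aic_table <- full$aic_table
  out$alpha <- alpha
  out$elimination_trace <- if (length(trace)) do.call(rbind, trace) else
    data.frame(dropped = character(), p_value = numeric())
  out$p_values <- if (length(current)) {
    vapply(sort(current), function(v) {
      reduced <- fit_one_family(fam, features[setdiff(current, v)], survival)
      pchisq(max(2 * (fit$log_likelihood - reduced$log_likelihood), 0),
             df = 1, lower.tail = FALSE)
    }, numeric(1))
  } else numeric(0)
  class(out) <- "parametric_os_model"
  out
}

#' Predict per-patient survival curves from a parametric OS model
#'
#' Evaluates the fitted family's survival function on a time grid for each
#' row of `newdata`, using the AFT linear predictor. Curves start at 1 and
#' are non-increasing by construction.
#'
#' @param model a `parametric_os_model`
#' @param newdata data frame containing every retained covariate
#' @param grid time grid in days (>= 0)
#' @return matrix of dim `nrow(newdata)` x `length(grid)`.
#' @export
predict_parametric_curves <- function(model, newdata, grid) {
  stopifnot(inherits(model, "parametric_os_model"))
  missing_cov <- setdiff(model$covariates, names(newdata))
  if (length(missing_cov))
    stop("newdata is missing retained covariate(s): ",
         paste(missing_cov, collapse = ", "))
  X <- cbind(`(Intercept)` = 1,
             as.matrix(newdata[model$covariates]))
  lp <- drop(X %*% model$coefficients[colnames(X)])
  sc <- model$scale
  S <- switch(model$family,
    exponential = function(t, lp) exp(-t / exp(lp)),
    weibull = function(t, lp) exp(-(t / exp(lp))^(1 / sc)),
    lognormal = function(t, lp) ifelse(t <= 0, 1, plnorm(t, lp, sc, lower.tail = FALSE)),
    loglogistic = function(t, lp) 1 / (1 + (t / exp(lp))^(1 / sc)))
  out <- vapply(grid, function(tt) S(tt, lp), numeric(length(lp)))
  out <- matrix(out, nrow = length(lp))
  out[, grid == 0] <- 1
  dimnames(out) <- list(rownames(newdata), grid)
  out
}
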