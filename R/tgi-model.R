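#' Biexponential tumor growth inhibition (TGI) trajectory
#'
#' Sum of longest diameters (SLD) under treatment is modeled as the sum of a
#' shrinking (treatment-sensitive) and a regrowing (resistant) exponential
#' component sharing the baseline size:
#' \deqn{SLD(t) = SLD_0 \left( e^{-K_S t} + e^{K_G t} - 1 \right)}
#' with \eqn{K_S} the shrinkage rate and \eqn{K_G} the regrowth rate, both in
#' 1/day. At \eqn{t = 0} the value is exactly \code{sld0}.
#'
#' @param t time since first dose in days (vectorized, must be >= 0)
#' @param sld0 baseline SLD in mm (> 0)
#' @param ks shrinkage rate, 1/day (> 0)
#' @param kg regrowth rate, 1/day (> 0)
#' @return SLD in mm, same length as the longest input.
#' @examples
#' biexp_sld(0, 50, 0.1, 0.01)    # 50
#' biexp_sld(84, 60, 0.08, 0.005) # nadir region
#' @export
biexp_sld <- function(t, sld0, ks, kg) {
  if (any(!is.finite(t)) || any(t < 0)) stop("t must be finite and >= 0")
  if (any(sld0 <= 0) || any(ks <= 0) || any(kg <= 0))
    stop("sld0, ks and kg must be strictly positive")
  sld0 * (exp(-ks * t) + exp(kg * t) - 1)
}

#' Time to tumor growth (TTG)
#'
#' The time at which the biexponential trajectory reaches its minimum and
#' regrowth begins. Setting the derivative of [biexp_sld()] to zero gives the
#' closed form \eqn{TTG = \log(K_S / K_G) / (K_S + K_G)}, clamped at 0 when
#' \eqn{K_S \le K_G} (a never-shrinking tumor regrows immediately).
#'
#' @param ks shrinkage rate, 1/day (> 0); vectorized
#' @param kg regrowth rate, 1/day (> 0); vectorized
#' @return TTG in days (>= 0).
#' @examples
#' ttg(0.2, 0.02)  # log(10) / 0.22
#' @export
ttg <- function(ks, kg) {
  if (any(ks <= 0) || any(kg <= 0)) stop("ks and kg must be strictly positive")
  pmax(0, log(ks / kg) / (ks + kg))
}

#' TGI evaluability filter
#'
#' A patient is TGI-evaluable when they have a baseline (time 0) measurement
#' and at least one post-baseline measurement; only those patients enter the
#' parametric TGI fit. The partition is exhaustive and disjoint.
#'
#' @param longitudinal data frame with columns `patient_id`, `time_days`,
#'   `sld_mm`
#' @return list with character vectors `evaluable` and `excluded`.
#' @export
evaluability_filter <- function(longitudinal) {
  stopifnot(all(c("patient_id", "time_days") %in% names(longitudinal)))
  ids <- unique(as.character(longitudinal$patient_id))
  has_base <- tapply(longitudinal$time_days, longitudinal$patient_id,
                     function(t) any(t == 0))
  has_post <- tapply(longitudinal$time_days, longitudinal$patient_id,
                     function(t) any(t > 0))
  ok <- ids[has_base[ids] & has_post[ids]]
  list(evaluable = sort(ok), excluded = sort(setdiff(ids, ok)))
}

# Penalized sum-of-squares objective on th = (log sld0, log ks, log kg).
# The optional prior adds a quadratic penalty toward population log-means
# weighted by the inverse IIV variances scaled by the residual variance,
# i.e. the MAP objective of the empirical-Bayes scheme.
tgi_objective <- function(th, t, y, prior = NULL) {
  sld0 <- exp(th[1]); ks <- exp(th[2]); kg <- exp(th[3])
  pred <- sld0 * (exp(-ks * t) + exp(pmin(kg * t, 500)) - 1)
  sse <- sum((y - pred)^2)
  if (!is.finite(sse)) return(1e30)  # keep L-BFGS-B on finite ground
  if (!is.null(prior)) {
    mu <- prior$mu
    w <- prior$sigma_mm^2 / pmax(prior$omega2, 1e-8)
    sse <- sse + sum(w * (th - mu)^2)
  }
  sse
}

tgi_gradient <- function(th, t, y, prior = NULL) {
  s0 <- exp(th[1]); ks <- exp(th[2]); kg <- exp(th[3])
  e1 <- exp(-ks * t); e2 <- exp(pmin(kg * t, 500))
  pred <- s0 * (e1 + e2 - 1)
  r <- y - pred
  g <- c(sum(-2 * r * pred),                 # d pred / d log(sld0) = pred
         sum(-2 * r * (-s0 * t * e1 * ks)),
         sum(-2 * r * (s0 * t * e2 * kg)))
  if (!is.null(prior)) {
    w <- prior$sigma_mm^2 / pmax(prior$omega2, 1e-8)
    g <- g + 2 * w * (th - prior$mu)
  }
  g
}

LOG_KG_LOWER <- log(1e-6)  # 1/day; regrowth below this is indistinguishable from 0

#' Fit the biexponential TGI model to one patient
#'
#' Least-squares fit on the log scale of (SLD0, KS, KG) to enforce positivity,
#' optionally penalized toward population means (an empirical-Bayes MAP fit)
#' when a `prior` is supplied. Three jittered starts guard against local
#' minima; the best SSE wins, ties broken by the first start.
#'
#' @param time_days,sld_mm the patient's measurement times and observed SLD
#' @param init optional list with elements `sld0`, `ks`, `kg` used as the
#'   central start
#' @param prior optional list with `mu` (length-3 log-scale means for
#'   log SLD0, log KS, log KG), `omega2` (length-3 IIV variances) and
#'   `sigma_mm` (residual SD); enables the MAP penalty
#' @param n_starts number of jittered starts (default 3)
#' @return list of class `tgi_individual` with `sld0_mm`, `ks_per_day`,
#'   `kg_per_day`, `ttg_days`, `fit_sse`, `converged`, `at_boundary`.
#' @export
fit_tgi_individual <- function(time_days, sld_mm, init = NULL, prior = NULL,
                               n_starts = 3, want_hessian = FALSE) {
  o <- order(time_days)
  t <- as.numeric(time_days)[o]; y <- as.numeric(sld_mm)[o]
  if (anyDuplicated(t)) stop("duplicate measurement times for one patient")
  if (length(t) < 3 && is.null(prior))
    stop("fewer than 3 measurements: under-determined without a prior")
  y0 <- if (any(t == 0)) y[t == 0] else max(y[1], 1)
  start <- if (!is.null(init)) {
    c(log(init$sld0), log(init$ks), log(init$kg))
  } else if (!is.null(prior)) {
    prior$mu
  } else {
    c(log(max(y0, 1)), log(0.02), log(0.003))
  }
  jitter_scale <- c(0.05, 0.5, 0.5)
  best <- NULL
  for (s in seq_len(n_starts)) {
    th0 <- if (s == 1) start else start + jitter_scale * tgi_start_jitter(s)
    fit <- tryCatch(
      optim(th0, tgi_objective, gr = tgi_gradient, t = t, y = y, prior = prior,
            method = "L-BFGS-B",
            lower = c(log(1e-2), log(1e-6), LOG_KG_LOWER),
            upper = c(log(1e4), log(1), log(0.2)),
            control = list(maxit = 500, factr = 1e1, pgtol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    th <- start
    res <- list(converged = FALSE, value = tgi_objective(th, t, y, prior), par = th)
  } else {
    res <- list(converged = best$convergence == 0, value = best$value,
                par = best$par)
  }
  hess <- if (want_hessian && !is.null(best)) {
    stats::optimHess(res$par, tgi_objective, t = t, y = y, prior = prior)
  } else NULL
  structure(list(
    sld0_mm = exp(res$par[1]),
    ks_per_day = exp(res$par[2]),
    kg_per_day = exp(res$par[3]),
    ttg_days = ttg(exp(res$par[2]), exp(res$par[3])),
    fit_sse = res$value,
    converged = res$converged,
    at_boundary = res$par[3] <= LOG_KG_LOWER + 1e-6,
    hessian = hess,
    n_obs = length(t)
  ), class = "tgi_individual")
}

# deterministic pseudo-jitter so fits stay reproducible without touching RNG
tgi_start_jitter <- function(s) {
  base <- sin(s * c(12.9898, 78.233, 37.719)) * 43758.5453
  2 * (base - floor(base)) - 1
}

#' Fit TGI population and individual parameters (empirical-Bayes alternation)
#'
#' Approximates the nonlinear mixed-effects fit by alternating (a) MAP
#' individual fits given the current population parameters and (b) moment
#' updates of the population parameters: per-group means of the individual
#' log-parameters, IIV variances as their variances, and a pooled residual SD.
#' Iterates until the relative change in population parameters falls below
#' `tol` or `max_iter` outer iterations.
#'
#' @param longitudinal data frame (`patient_id`, `time_days`, `sld_mm`)
#' @param baseline data frame with `patient_id` and `tumor_type` (group label)
#' @param tol outer-loop relative-change tolerance (default 1e-4)
#' @param max_iter maximum outer iterations (default 50)
#' @return list of class `tgi_population_fit` with elements `population`
#'   (per-group log-means, omega2, sigma_mm, n_evaluable) and `individuals`
#'   (one row per evaluable patient with SLD0/KS/KG/TTG and diagnostics).
#' @export
fit_tgi_population <- function(longitudinal, baseline, tol = 1e-4,
                               max_iter = 50) {
  ev <- evaluability_filter(longitudinal)$evaluable
  groups <- setNames(as.character(baseline$tumor_type),
                     as.character(baseline$patient_id))
  ev <- ev[ev %in% names(groups)]
  if (length(ev) < 2) stop("need at least 2 evaluable patients")
  split_data <- split(longitudinal[longitudinal$patient_id %in% ev, ],
                      factor(longitudinal$patient_id[longitudinal$patient_id %in% ev],
                             levels = ev))
  glabels <- groups[ev]
  glv <- sort(unique(glabels))
  pname <- c("logSLD0", "logKS", "logKG")

  log_params <- function(fits) {
    th <- t(vapply(fits, function(f) {
      log(c(f$sld0_mm, f$ks_per_day, f$kg_per_day))
    }, numeric(3)))
    colnames(th) <- pname
    th
  }
  pooled_sigma <- function(fits, idx = seq_along(ev)) {
    resid2 <- 0; nres <- 0
    for (i in idx) {
      d <- split_data[[i]]; f <- fits[[i]]
      pred <- biexp_sld(d$time_days, f$sld0_mm, f$ks_per_day, f$kg_per_day)
      resid2 <- resid2 + sum((d$sld_mm - pred)^2)
      nres <- nres + nrow(d)
    }
    sqrt(max(resid2 / max(nres - 3 * length(idx), 1), 1e-6))
  }
  group_means <- function(th) {
    m <- vapply(glv, function(g) colMeans(th[glabels == g, , drop = FALSE]),
                numeric(3))
    dimnames(m) <- list(pname, glv)
    m
  }

  # Stage 0: unpenalized least-squares fits seed the population honestly;
  # patients with < 3 measurements wait for the MAP stage.
  fits <- setNames(vector("list", length(ev)), ev)
  free_ok <- logical(length(ev))
  for (i in seq_along(ev)) {
    d <- split_data[[i]]
    if (nrow(d) >= 3) {
      fits[[i]] <- fit_tgi_individual(d$time_days, d$sld_mm, n_starts = 3)
      free_ok[i] <- fits[[i]]$converged && !fits[[i]]$at_boundary
    }
  }
  if (!any(free_ok)) stop("no patient admits an unpenalized TGI fit")
  th0 <- log_params(fits[free_ok])
  mu0 <- vapply(glv, function(g) {
    sel <- glabels[free_ok] == g
    if (any(sel)) colMeans(th0[sel, , drop = FALSE]) else colMeans(th0)
  }, numeric(3))
  dimnames(mu0) <- list(pname, glv)
  pop <- list(mu = mu0,
              omega2 = pmin(pmax(apply(th0, 2, stats::var), 0.02), 4),
              sigma_mm = pooled_sigma(fits, which(free_ok)))

  # MAP alternation. The inter-individual variance update adds the Laplace
  # posterior variance of each MAP fit to the variance of the MAP point
  # estimates; the plain moment update collapses omega2 to zero for weakly
  # identified parameters (notably KS when shrinkage is mostly over before
  # the first follow-up visit) and freezes the population mean.
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    postvar <- matrix(0, length(ev), 3)
    for (i in seq_along(ev)) {
      d <- split_data[[i]]
      prior <- list(mu = pop$mu[, glabels[i]], omega2 = pop$omega2,
                    sigma_mm = pop$sigma_mm)
      init <- if (!is.null(fits[[i]]))
        list(sld0 = fits[[i]]$sld0_mm, ks = fits[[i]]$ks_per_day,
             kg = fits[[i]]$kg_per_day) else NULL
      fits[[i]] <- fit_tgi_individual(d$time_days, d$sld_mm, init = init,
                                      prior = prior, n_starts = 1,
                                      want_hessian = TRUE)
      pv <- rep(pop$omega2 / 2, length.out = 3)
      if (!is.null(fits[[i]]$hessian)) {
        # negative log posterior = objective / (2 sigma^2)
        cv <- tryCatch(2 * pop$sigma_mm^2 * diag(solve(fits[[i]]$hessian)),
                       error = function(e) NULL)
        if (!is.null(cv) && all(is.finite(cv)) && all(cv > 0))
          pv <- pmin(cv, pop$omega2)
      }
      postvar[i, ] <- pv
    }
    th <- log_params(fits)
    mu_new <- group_means(th)
    grp_sizes <- table(glabels)[glv]
    omega_new <- vapply(seq_along(pname), function(p) {
      ok <- grp_sizes >= 2
      if (!any(ok)) return(NA_real_)
      within_var <- vapply(glv[ok], function(g) {
        sel <- glabels == g
        stats::var(th[sel, p]) + mean(postvar[sel, p])
      }, numeric(1))
      sum(within_var * (grp_sizes[ok] - 1)) / sum(grp_sizes[ok] - 1)
    }, numeric(1))
    sigma_new <- pooled_sigma(fits)
    rel <- max(abs(mu_new - pop$mu) / pmax(abs(pop$mu), 0.1),
               abs(sigma_new - pop$sigma_mm) / max(pop$sigma_mm, 0.1))
    pop$mu <- mu_new
    pop$omega2 <- pmax(setNames(omega_new, pname), 1e-4)
    pop$sigma_mm <- sigma_new
    if (rel < tol) break
  }
  individuals <- data.frame(
    patient_id = ev,
    tumor_type = unname(glabels),
    sld0_mm = vapply(fits, `[[`, numeric(1), "sld0_mm"),
    ks_per_day = vapply(fits, `[[`, numeric(1), "ks_per_day"),
    kg_per_day = vapply(fits, `[[`, numeric(1), "kg_per_day"),
    ttg_days = vapply(fits, `[[`, numeric(1), "ttg_days"),
    fit_sse = vapply(fits, `[[`, numeric(1), "fit_sse"),
    converged = vapply(fits, `[[`, logical(1), "converged"),
    at_boundary = vapply(fits, `[[`, logical(1), "at_boundary"),
    row.names = NULL, stringsAsFactors = FALSE)
  individuals$logKS <- log(individuals$ks_per_day)
  individuals$logKG <- log(individuals$kg_per_day)
  group_means <- pop$mu
  omega2_by_group <- vapply(c("logSLD0", "logKS", "logKG"), function(p) {
    v <- tapply(log(individuals[[switch(p, logSLD0 = "sld0_mm",
                                        logKS = "ks_per_day",
                                        logKG = "kg_per_day")]]),
                individuals$tumor_type, stats::var)
    v
  }, numeric(length(unique(glabels))))
  structure(list(
    population = list(mu = group_means, omega2 = pop$omega2,
                      omega2_by_group = omega2_by_group,
                      sigma_mm = pop$sigma_mm,
                      n_evaluable = as.integer(table(glabels)),
                      groups = names(table(glabels)),
                      iterations = iter),
    individuals = individuals
  ), class = "tgi_population_fit")
}

#' Goodness-of-fit summary for TGI individual fits
#'
#' Residuals at the observed times per patient: observed vs predicted pairs,
#' per-patient R-squared and residual SD, and the pooled residual SD.
#'
#' @param individuals data frame as returned in
#'   `fit_tgi_population()$individuals` (needs `patient_id`, `sld0_mm`,
#'   `ks_per_day`, `kg_per_day`)
#' @param longitudinal the measurement table the fits were computed from
#' @return list with `per_patient` (patient_id, n_obs, r_squared, resid_sd),
#'   `pairs` (patient_id, time_days, observed, predicted, residual) and
#'   `pooled_resid_sd`.
#' @export
tgi_goodness_of_fit <- function(individuals, longitudinal) {
  if (nrow(individuals) == 0) {
    return(list(per_patient = data.frame(), pairs = data.frame(),
                pooled_resid_sd = NA_real_))
  }
  idx <- match(as.character(longitudinal$patient_id),
               as.character(individuals$patient_id))
  keep <- !is.na(idx)
  d <- longitudinal[keep, ]
  ind <- individuals[idx[keep], ]
  pred <- biexp_sld(d$time_days, ind$sld0_mm, ind$ks_per_day, ind$kg_per_day)
  pairs <- data.frame(patient_id = d$patient_id, time_days = d$time_days,
                      observed = d$sld_mm, predicted = pred,
                      residual = d$sld_mm - pred)
  per <- do.call(rbind, lapply(split(pairs, pairs$patient_id), function(p) {
    ss_res <- sum(p$residual^2)
    ss_tot <- sum((p$observed - mean(p$observed))^2)
    data.frame(patient_id = p$patient_id[1], n_obs = nrow(p),
               r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
               resid_sd = if (nrow(p) > 1) stats::sd(p$residual) else NA_real_)
  }))
  rownames(per) <- NULL
  list(per_patient = per, pairs = pairs,
       pooled_resid_sd = sqrt(mean(pairs$residual^2)))
}
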