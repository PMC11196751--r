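#' Cohort configuration for the synthetic trial generator
#'
#' Describes a multi-tumor-type cohort: per-group sizes and log-scale means of
#' the individual TGI parameters, shared inter-individual variability (IIV)
#' variances, an additive residual SD on observed SLD, a common visit
#' schedule, and a per-visit dropout probability.
#'
#' @param groups data frame with columns `tumor_type`, `n_patients`,
#'   `mu_logKS`, `mu_logKG`, `mu_logSLD0`
#' @param omega2_logKS,omega2_logKG,omega2_logSLD0 IIV variances on the log
#'   scale (>= 0)
#' @param sigma_sld_mm additive residual SD of observed SLD in mm (>= 0)
#' @param visit_schedule_days ascending measurement days; must start at 0
#' @param dropout_prob_per_visit probability in `[0, 1]` that a patient drops
#'   out at each post-baseline visit (monotone: all later visits are lost too)
#' @param seed integer seed for trajectories and baseline covariates
#' @return validated list of class `cohort_config`.
#' @export
cohort_config <- function(groups,
                          omega2_logKS = 0.25, omega2_logKG = 0.25,
                          omega2_logSLD0 = 0.1,
                          sigma_sld_mm = 5,
                          visit_schedule_days = round(seq(0, 365, length.out = 8)),
                          dropout_prob_per_visit = 0.05,
                          seed = 1L) {
  stopifnot(is.data.frame(groups),
            all(c("tumor_type", "n_patients", "mu_logKS", "mu_logKG",
                  "mu_logSLD0") %in% names(groups)))
  num <- c(omega2_logKS, omega2_logKG, omega2_logSLD0, sigma_sld_mm,
           visit_schedule_days, dropout_prob_per_visit, seed,
           groups$n_patients, groups$mu_logKS, groups$mu_logKG,
           groups$mu_logSLD0)
  if (any(!is.finite(num))) stop("config values must be finite")
  if (omega2_logKS < 0 || omega2_logKG < 0 || omega2_logSLD0 < 0)
    stop("IIV variances must be >= 0")
  if (sigma_sld_mm < 0) stop("sigma_sld_mm must be >= 0")
  if (length(visit_schedule_days) == 0) stop("empty visit schedule")
  if (visit_schedule_days[1] != 0 ||
      any(diff(visit_schedule_days) <= 0))
    stop("visit_schedule_days must start at 0 and be strictly increasing")
  if (dropout_prob_per_visit < 0 || dropout_prob_per_visit > 1)
    stop("dropout_prob_per_visit must be in [0, 1]")
  if (any(groups$n_patients < 1)) stop("each group needs n_patients >= 1")
  structure(list(groups = groups, omega2_logKS = omega2_logKS,
                 omega2_logKG = omega2_logKG, omega2_logSLD0 = omega2_logSLD0,
                 sigma_sld_mm = sigma_sld_mm,
                 visit_schedule_days = visit_schedule_days,
                 dropout_prob_per_visit = dropout_prob_per_visit,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Default cohort emulating a multi-tumor-type targeted-therapy trial
#'
#' Four groups sized 313 (NSCLC), 224 (MTC), 28 (OTHER_FUS) and 20
#' (OTHER_ALT). MTC carries the slowest regrowth (best prognosis) and the
#' small fusion/alteration groups the fastest, reproducing the qualitative
#' ordering of the TGI-metric distributions across tumor types.
#'
#' @param ... overrides passed through to [cohort_config()]
#' @return a `cohort_config`.
#' @export
default_cohort_config <- function(...) {
  groups <- data.frame(
    tumor_type = c("NSCLC", "MTC", "OTHER_FUS", "OTHER_ALT"),
    n_patients = c(313L, 224L, 28L, 20L),
    mu_logKS = log(c(0.030, 0.020, 0.035, 0.035)),
    mu_logKG = log(c(0.0040, 0.0015, 0.0060, 0.0070)),
    mu_logSLD0 = log(c(60, 45, 55, 55)))
  cohort_config(groups, ...)
}

#' Survival-generation configuration (AFT)
#'
#' Survival times are drawn from an accelerated-failure-time model whose
#' linear predictor combines the patient's true `logKG` with baseline
#' covariates: `log T = intercept + beta . x + scale * eps`, with `eps`
#' standard normal (lognormal family) or standard minimum Gumbel (weibull
#' family). Censoring is the minimum of an exponential random-censoring time
#' and a fixed administrative cutoff.
#'
#' @param family `"lognormal"` or `"weibull"`
#' @param intercept AFT intercept (log-days scale)
#' @param beta named coefficient vector; names must be `logKG` and/or baseline
#'   covariate columns (`ecog`, `hgb`, `albu`, `nlr`, `liver_met`,
#'   `n_tumor_sites`, `neu`, `ysd`, `sld0_true_mm`, `race_asian`, `sex`)
#' @param scale AFT scale (> 0)
#' @param admin_censor_day administrative censoring day (> 0)
#' @param random_censor_rate exponential censoring rate per day (>= 0)
#' @param seed integer seed for the survival draw (separate from the
#'   trajectory seed so each can be held fixed)
#' @return validated list of class `surv_gen_config`.
#' @export
surv_gen_config <- function(family = c("lognormal", "weibull"),
                            intercept = 0.4,
                            beta = c(logKG = -0.9, ecog = -0.3, albu = 0.4,
                                     liver_met = -0.3),
                            scale = 0.8,
                            admin_censor_day = 1200,
                            random_censor_rate = 1 / 3000,
                            seed = 2L) {
  family <- match.arg(family)
  if (!all(is.finite(c(intercept, beta, scale, admin_censor_day,
                       random_censor_rate, seed))))
    stop("config values must be finite")
  if (scale <= 0) stop("scale must be > 0")
  if (admin_censor_day <= 0) stop("admin_censor_day must be > 0")
  if (random_censor_rate < 0) stop("random_censor_rate must be >= 0")
  if (is.null(names(beta)) || any(names(beta) == ""))
    stop("beta must be a named vector")
  structure(list(family = family, intercept = intercept, beta = beta,
                 scale = scale, admin_censor_day = admin_censor_day,
                 random_censor_rate = random_censor_rate,
                 seed = as.integer(seed)),
            class = "surv_gen_config")
}

# Baseline covariate draws: independent simple parametric families with
# plausible oncology-trial marginals (the source trial publishes none).
draw_baseline_covariates <- function(n) {
  data.frame(
    ecog = sample(0:2, n, replace = TRUE, prob = c(0.40, 0.45, 0.15)),
    hgb = pmax(rnorm(n, 12.5, 1.5), 6),           # g/dL
    albu = pmax(rnorm(n, 4.0, 0.45), 1.5),        # g/dL
    nlr = rlnorm(n, log(3), 0.5),                 # ratio
    liver_met = rbinom(n, 1, 0.25),
    n_tumor_sites = 1L + rpois(n, 1.5),
    neu = rlnorm(n, log(4.5), 0.35),              # 10^9 cells/L
    ysd = rexp(n, 1 / 2),                         # years since diagnosis
    race_asian = rbinom(n, 1, 0.3),
    sex = rbinom(n, 1, 0.5))
}

#' Simulate a multi-tumor-type trial cohort
#'
#' Draws individual (SLD0, KS, KG) log-normally around the group means, builds
#' noisy biexponential SLD trajectories (additive normal residual, clamped at
#' 0 mm), applies monotone dropout, draws independent baseline covariates, and
#' generates right-censored AFT survival outcomes driven by the true `logKG`
#' and baseline covariates. Identical configs (including seeds) give
#' bit-identical tables.
#'
#' @param config a [cohort_config()]
#' @param surv_config a [surv_gen_config()]
#' @return list of class `tgi_cohort` with data frames `longitudinal`
#'   (`patient_id`, `time_days`, `sld_mm`), `baseline` (covariates +
#'   `tumor_type`), `survival` (`patient_id`, `time_days`, `event`) and
#'   `truth` (the generating per-patient parameters and uncensored times).
#' @export
simulate_cohort <- function(config, surv_config) {
  stopifnot(inherits(config, "cohort_config"),
            inherits(surv_config, "surv_gen_config"))
  n_total <- sum(config$groups$n_patients)
  withr_seed <- function(seed, code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code()
  }
  ids <- sprintf("P%04d", seq_len(n_total))
  tumor_type <- rep(config$groups$tumor_type, config$groups$n_patients)

  traj <- withr_seed(config$seed, function() {
    mu_ks <- rep(config$groups$mu_logKS, config$groups$n_patients)
    mu_kg <- rep(config$groups$mu_logKG, config$groups$n_patients)
    mu_s0 <- rep(config$groups$mu_logSLD0, config$groups$n_patients)
    ks <- exp(rnorm(n_total, mu_ks, sqrt(config$omega2_logKS)))
    kg <- exp(rnorm(n_total, mu_kg, sqrt(config$omega2_logKG)))
    sld0 <- exp(rnorm(n_total, mu_s0, sqrt(config$omega2_logSLD0)))
    cov <- draw_baseline_covariates(n_total)
    visits <- config$visit_schedule_days
    nv <- length(visits)
    # monotone dropout: first post-baseline visit failing the Bernoulli draw
    # removes that visit and all later ones
    keep_n <- rep(nv, n_total)
    if (config$dropout_prob_per_visit > 0 && nv > 1) {
      u <- matrix(runif(n_total * (nv - 1)), n_total, nv - 1)
      for (i in seq_len(n_total)) {
        gone <- which(u[i, ] < config$dropout_prob_per_visit)
        if (length(gone)) keep_n[i] <- gone[1]
      }
    }
    long <- data.frame(
      patient_id = rep(ids, keep_n),
      time_days = unlist(lapply(keep_n, function(k) visits[seq_len(k)])))
    true_sld <- biexp_sld(long$time_days,
                          rep(sld0, keep_n), rep(ks, keep_n), rep(kg, keep_n))
    noise <- if (config$sigma_sld_mm > 0)
      rnorm(nrow(long), 0, config$sigma_sld_mm) else 0
    long$sld_mm <- pmax(true_sld + noise, 0)
    list(long = long, ks = ks, kg = kg, sld0 = sld0, cov = cov)
  })

  baseline <- cbind(
    data.frame(patient_id = ids, tumor_type = tumor_type,
               stringsAsFactors = FALSE),
    traj$cov)
  baseline$sld0_true_mm <- traj$sld0

  surv <- withr_seed(surv_config$seed, function() {
    x <- cbind(logKG = log(traj$kg), as.matrix(baseline[names(draw_baseline_covariates(0))]),
               sld0_true_mm = traj$sld0)
    bn <- names(surv_config$beta)
    missing_cov <- setdiff(bn, colnames(x))
    if (length(missing_cov))
      stop("unknown beta covariates: ", paste(missing_cov, collapse = ", "))
    lp <- surv_config$intercept + drop(x[, bn, drop = FALSE] %*% surv_config$beta)
    eps <- switch(surv_config$family,
                  lognormal = rnorm(n_total),
                  weibull = log(rexp(n_total)))
    t_event <- exp(lp + surv_config$scale * eps)
    t_cens <- if (surv_config$random_censor_rate > 0)
      rexp(n_total, surv_config$random_censor_rate) else rep(Inf, n_total)
    obs <- pmin(t_event, t_cens, surv_config$admin_censor_day)
    data.frame(patient_id = ids,
               time_days = pmax(obs, 0.5),
               event = as.integer(t_event <= pmin(t_cens, surv_config$admin_censor_day)),
               t_event_true = t_event,
               lp_true = lp)
  })

  structure(list(
    longitudinal = traj$long,
    baseline = baseline,
    survival = surv[c("patient_id", "time_days", "event")],
    truth = data.frame(patient_id = ids, tumor_type = tumor_type,
                       sld0 = traj$sld0, ks = traj$ks, kg = traj$kg,
                       logKG = log(traj$kg),
                       ttg = ttg(traj$ks, traj$kg),
                       t_event_true = surv$t_event_true,
                       lp_true = surv$lp_true,
                       stringsAsFactors = FALSE),
    config = config, surv_config = surv_config
  ), class = "tgi_cohort")
}

#' Write a simulated cohort to CSV files plus a seed manifest
#'
#' @param cohort a `tgi_cohort` from [simulate_cohort()]
#' @param dir output directory (created if needed)
#' @return invisibly, the named vector of file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "tgi_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(longitudinal = file.path(dir, "longitudinal.csv"),
             baseline = file.path(dir, "baseline.csv"),
             survival = file.path(dir, "survival.csv"),
             manifest = file.path(dir, "cohort_manifest.json"))
  write.csv(cohort$longitudinal, paths["longitudinal"], row.names = FALSE)
  write.csv(cohort$baseline, paths["baseline"], row.names = FALSE)
  write.csv(cohort$survival, paths["survival"], row.names = FALSE)
  jsonlite::write_json(
    list(seed_trajectory = cohort$config$seed,
         seed_survival = cohort$surv_config$seed,
         n_patients = nrow(cohort$baseline),
         groups = as.list(table(cohort$baseline$tumor_type))),
    paths["manifest"], auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
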