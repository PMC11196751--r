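# Shared fixtures, built once per test run and cached: several tests (module
# and acceptance) reuse the same simulated cohorts and fitted models.
.fx_cache <- new.env(parent = emptyenv())

fx_memo <- function(key, builder) {
  if (!exists(key, .fx_cache)) assign(key, builder(), .fx_cache)
  get(key, .fx_cache)
}

# The TGI recovery world: 300 patients, 8 visits over 365 days, IIV variance
# 0.25 on log KS / log KG, residual SD 5 mm, no dropout.
fx_recovery300 <- function() fx_memo("recovery300", function() {
  groups <- data.frame(tumor_type = "A", n_patients = 300L,
                       mu_logKS = log(0.03), mu_logKG = log(0.004),
                       mu_logSLD0 = log(60))
  cc <- cohort_config(groups, omega2_logKS = 0.25, omega2_logKG = 0.25,
                      omega2_logSLD0 = 0.1, sigma_sld_mm = 5,
                      dropout_prob_per_visit = 0, seed = 7)
  co <- simulate_cohort(cc, surv_gen_config(seed = 8))
  fit <- fit_tgi_population(co$longitudinal, co$baseline)
  list(cohort = co, fit = fit)
})

# A KG-driven survival world: 250 patients, lognormal AFT with beta_logKG = -1
# and no other covariate effects, moderate censoring.
fx_kg_cohort <- function() fx_memo("kg_cohort", function() {
  groups <- data.frame(tumor_type = "A", n_patients = 250L,
                       mu_logKS = log(0.03), mu_logKG = log(0.004),
                       mu_logSLD0 = log(60))
  cc <- cohort_config(groups, dropout_prob_per_visit = 0.05, seed = 11)
  sc <- surv_gen_config(beta = c(logKG = -1), intercept = 1.2, scale = 0.7,
                        seed = 12)
  co <- simulate_cohort(cc, sc)
  tgi <- data.frame(patient_id = co$truth$patient_id,
                    ks_per_day = co$truth$ks, kg_per_day = co$truth$kg,
                    ttg_days = co$truth$ttg)
  fm <- build_feature_matrix(tgi, co$baseline)
  list(cohort = co, features = fm, sc = sc,
       train_idx = 1:175, test_idx = 176:250)
})

fx_kg_model <- function() fx_memo("kg_model", function() {
  fx <- fx_kg_cohort()
  train_ml_survival(fx$features, fx$cohort$survival)
})

# small KG-driven cohort generator for replicate-based tests
sim_kg_cohort <- function(n, seed_traj, seed_surv, beta = c(logKG = -1),
                          dropout = 0.05) {
  groups <- data.frame(tumor_type = "A", n_patients = as.integer(n),
                       mu_logKS = log(0.03), mu_logKG = log(0.004),
                       mu_logSLD0 = log(60))
  cc <- cohort_config(groups, dropout_prob_per_visit = dropout,
                      seed = seed_traj)
  sc <- surv_gen_config(beta = beta, intercept = 1.2, scale = 0.7,
                        seed = seed_surv)
  simulate_cohort(cc, sc)
}

truth_features <- function(co) {
  tgi <- data.frame(patient_id = co$truth$patient_id,
                    ks_per_day = co$truth$ks, kg_per_day = co$truth$kg,
                    ttg_days = co$truth$ttg)
  build_feature_matrix(tgi, co$baseline)
}

# 4-patient toy longitudinal fixture used by the evaluability examples
toy_longitudinal <- function() {
  data.frame(
    patient_id = c("A", "A", "A", "B", "C", "C", "D"),
    time_days = c(0, 42, 84, 0, 0, 56, 42),
    sld_mm = c(50, 40, 45, 60, 55, 50, 70))
}

# plain golden-section minimizer, the independent oracle for TTG
golden_min <- function(f, lo, hi, tol = 1e-9, max_iter = 200) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c <- b - gr * (b - a); d <- a + gr * (b - a)
  fc <- f(c); fd <- f(d)
  for (i in seq_len(max_iter)) {
    if (b - a < tol) break
    if (fc < fd) {
      b <- d; d <- c; fd <- fc
      c <- b - gr * (b - a); fc <- f(c)
    } else {
      a <- c; c <- d; fc <- fd
      d <- a + gr * (b - a); fd <- f(d)
    }
  }
  (a + b) / 2
}
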