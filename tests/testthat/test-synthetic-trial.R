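test_that("config invariants are enforced", {
  g <- data.frame(tumor_type = "A", n_patients = 5L, mu_logKS = log(0.03),
                  mu_logKG = log(0.004), mu_logSLD0 = log(60))
  expect_error(cohort_config(g, omega2_logKS = -1), "variances")
  expect_error(cohort_config(g, sigma_sld_mm = -2), "sigma")
  expect_error(cohort_config(g, visit_schedule_days = numeric(0)), "empty")
  expect_error(cohort_config(g, visit_schedule_days = c(10, 20)), "start at 0")
  expect_error(cohort_config(g, visit_schedule_days = c(0, 20, 20)),
               "strictly increasing")
  expect_error(cohort_config(g, dropout_prob_per_visit = 1.5), "dropout")
  g$n_patients <- 0L
  expect_error(cohort_config(g), "n_patients")
  g$n_patients <- 5L
  g$mu_logKG <- NA
  expect_error(cohort_config(g), "finite")
  expect_error(surv_gen_config(scale = 0), "scale")
  expect_error(surv_gen_config(admin_censor_day = -1), "admin")
  expect_error(surv_gen_config(beta = c(1, 2)), "named")
})

test_that("group sizes match the configured trial structure", {
  co <- simulate_cohort(default_cohort_config(seed = 3),
                        surv_gen_config(seed = 4))
  expect_equal(nrow(co$baseline), 585L)
  expect_equal(sum(co$baseline$tumor_type == "NSCLC"), 313L)
  expect_equal(sum(co$baseline$tumor_type == "MTC"), 224L)
  expect_equal(sum(co$baseline$tumor_type == "OTHER_FUS"), 28L)
  expect_equal(sum(co$baseline$tumor_type == "OTHER_ALT"), 20L)
  # patient sets agree across the three tables
  expect_setequal(unique(co$longitudinal$patient_id), co$baseline$patient_id)
  expect_setequal(co$survival$patient_id, co$baseline$patient_id)
  expect_true(all(co$survival$time_days <= 1200))
  expect_true(all(co$survival$event %in% 0:1))
})

test_that("noise-free, dropout-free trajectories equal the model exactly", {
  g <- data.frame(tumor_type = "A", n_patients = 20L, mu_logKS = log(0.03),
                  mu_logKG = log(0.004), mu_logSLD0 = log(60))
  cc <- cohort_config(g, sigma_sld_mm = 0, dropout_prob_per_visit = 0,
                      seed = 5)
  co <- simulate_cohort(cc, surv_gen_config(seed = 6))
  tr <- co$truth[match(co$longitudinal$patient_id, co$truth$patient_id), ]
  expected <- biexp_sld(co$longitudinal$time_days, tr$sld0, tr$ks, tr$kg)
  expect_equal(co$longitudinal$sld_mm, expected, tolerance = 1e-12)
  nv <- length(cc$visit_schedule_days)
  expect_equal(nrow(co$longitudinal), 20L * nv)
})

test_that("identical seeds give bit-identical tables; seeds are separable", {
  g <- data.frame(tumor_type = "A", n_patients = 30L, mu_logKS = log(0.03),
                  mu_logKG = log(0.004), mu_logSLD0 = log(60))
  co1 <- simulate_cohort(cohort_config(g, seed = 9), surv_gen_config(seed = 10))
  co2 <- simulate_cohort(cohort_config(g, seed = 9), surv_gen_config(seed = 10))
  expect_identical(co1$longitudinal, co2$longitudinal)
  expect_identical(co1$baseline, co2$baseline)
  expect_identical(co1$survival, co2$survival)
  # changing only the survival seed leaves trajectories untouched
  co3 <- simulate_cohort(cohort_config(g, seed = 9), surv_gen_config(seed = 99))
  expect_identical(co1$longitudinal, co3$longitudinal)
  expect_false(identical(co1$survival$time_days, co3$survival$time_days))
})

test_that("marginals and censoring behave as configured at n = 5000", {
  g <- data.frame(tumor_type = "A", n_patients = 5000L, mu_logKS = log(0.03),
                  mu_logKG = log(0.004), mu_logSLD0 = log(60))
  cc <- cohort_config(g, seed = 21)
  rates <- c(0, 1 / 2000, 1 / 500)
  cens_frac <- vapply(rates, function(r) {
    co <- simulate_cohort(cc, surv_gen_config(random_censor_rate = r, seed = 22))
    mean(co$survival$event == 0)
  }, numeric(1))
  expect_true(all(diff(cens_frac) > 0))
  co <- simulate_cohort(cc, surv_gen_config(seed = 22))
  se <- sqrt(0.25 / 5000)
  expect_lt(abs(mean(log(co$truth$ks)) - log(0.03)), 3 * se)
  expect_lt(abs(mean(log(co$truth$kg)) - log(0.004)), 3 * se)
})

test_that("AFT survival generation matches the closed-form median", {
  g <- data.frame(tumor_type = c("LO", "HI"), n_patients = c(1000L, 1000L),
                  mu_logKS = log(0.03),
                  mu_logKG = log(c(0.002, 0.008)), mu_logSLD0 = log(60))
  cc <- cohort_config(g, seed = 31)
  sc <- surv_gen_config(beta = c(logKG = -1), intercept = 1.2, scale = 0.7,
                        admin_censor_day = 1e9, random_censor_rate = 0,
                        seed = 32)
  co <- simulate_cohort(cc, sc)
  tt <- co$truth
  med_lo <- median(tt$t_event_true[tt$tumor_type == "LO"])
  med_hi <- median(tt$t_event_true[tt$tumor_type == "HI"])
  expect_gt(med_lo, med_hi)  # higher mu_logKG -> shorter survival
  # per-group closed form: median of lognormal AFT is exp(lp)
  for (grp in c("LO", "HI")) {
    sel <- tt$tumor_type == grp
    expect_lt(abs(log(median(tt$t_event_true[sel])) -
                    log(median(exp(tt$lp_true[sel])))), 0.1)
  }
})

test_that("dropout is monotone and removes later visits only", {
  g <- data.frame(tumor_type = "A", n_patients = 200L, mu_logKS = log(0.03),
                  mu_logKG = log(0.004), mu_logSLD0 = log(60))
  cc <- cohort_config(g, dropout_prob_per_visit = 0.3, seed = 41)
  co <- simulate_cohort(cc, surv_gen_config(seed = 42))
  sched <- cc$visit_schedule_days
  for (d in split(co$longitudinal, co$longitudinal$patient_id)) {
    # visits are always a prefix of the schedule
    expect_identical(sort(d$time_days), sched[seq_len(nrow(d))])
  }
  expect_lt(nrow(co$longitudinal), 200 * length(sched))
})

test_that("cohorts round-trip to CSV with a manifest", {
  g <- data.frame(tumor_type = "A", n_patients = 10L, mu_logKS = log(0.03),
                  mu_logKG = log(0.004), mu_logSLD0 = log(60))
  co <- simulate_cohort(cohort_config(g, seed = 51), surv_gen_config(seed = 52))
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)
  expect_true(all(file.exists(paths)))
  back <- read.csv(paths["longitudinal"])
  expect_equal(nrow(back), nrow(co$longitudinal))
  man <- jsonlite::read_json(paths["manifest"])
  expect_equal(man$seed_trajectory, 51L)
  expect_equal(man$n_patients, 10L)
})
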