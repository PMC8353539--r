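test_that("time-dependent AUC reduces to Mann-Whitney without censoring", {
  # perfectly separating scores
  time <- c(10, 20, 30, 80, 90, 100)
  event <- c(1, 1, 1, 0, 0, 0)
  risk <- c(9, 8, 7, 1, 2, 3)
  expect_equal(as.numeric(time_dependent_auc(risk, time, event, 60)), 1)

  # uncensored toy set: exhaustive pairwise enumeration oracle
  set.seed(12)
  time <- c(12, 25, 40, 70, 90, 110)
  event <- c(1, 1, 1, 0, 0, 0)   # controls survive past the horizon
  risk <- c(2.5, 1.0, 3.0, 2.0, 0.5, 2.7)
  cases <- which(time <= 60 & event == 1)
  ctrls <- which(time > 60)
  conc <- 0
  for (i in cases) for (j in ctrls)
    conc <- conc + (risk[i] > risk[j]) + 0.5 * (risk[i] == risk[j])
  expect_equal(as.numeric(time_dependent_auc(risk, time, event, 60)),
               conc / (length(cases) * length(ctrls)))
  expect_error(time_dependent_auc(risk, time, rep(0, 6), 60), "cases")
})

test_that("the model's risk scores discriminate better than noise", {
  p <- reference_params()
  g <- generate_cohort(cohort_config(n = 3000, seed = 51,
                                     missingness = no_missingness), p)
  co <- g$cohort
  occ <- curemsm:::cohort_occupancy(co, p, 60)
  risk <- rowSums(occ[, c("lrr_dead", "dm_dead", "persistent_dead",
                          "dead_norec"), 1])
  died <- !is.na(co$death_time)
  t_os <- ifelse(died, co$death_time, co$followup_time)
  auc_model <- as.numeric(time_dependent_auc(risk, t_os, died, 60))
  set.seed(1)
  auc_null <- as.numeric(time_dependent_auc(runif(nrow(co)), t_os, died,
                                            60))
  expect_gt(auc_model, auc_null + 0.1)
  expect_gt(auc_model, 0.6)
})

test_that("concordance matches exhaustive enumeration and its symmetries", {
  set.seed(33)
  n <- 20
  time <- rexp(n, 1 / 40)          # continuous: no tied times
  event <- runif(n) < 0.6
  risk <- rnorm(n)
  num <- den <- 0
  for (i in 1:n) for (j in 1:n) {
    if (!event[i] || !(time[j] > time[i])) next
    den <- den + 1
    num <- num + (risk[i] > risk[j]) + 0.5 * (risk[i] == risk[j])
  }
  expect_equal(concordance_index(risk, time, event), num / den)
  # all-tied scores give exactly one half
  expect_equal(concordance_index(rep(1, n), time, event), 0.5)
  # antitone transform flips concordance
  expect_equal(concordance_index(-risk, time, event),
               1 - concordance_index(risk, time, event))
  # agreement with the survival package on the same data
  cfit <- survival::concordance(survival::Surv(time, event) ~ risk,
                                reverse = TRUE)
  expect_equal(concordance_index(risk, time, event),
               unname(cfit$concordance), tolerance = 1e-10)
})

test_that("calibration rows sum to one and support ct/p16 strata", {
  p <- reference_params()
  g <- generate_cohort(cohort_config(n = 2500, seed = 53,
                                     missingness = no_missingness), p)
  cal <- calibration_by_strata(g$cohort, p, strata = c("ct", "p16"),
                               horizons = c(24, 60))
  expect_setequal(unique(cal$stratum_var), c("ct", "p16"))
  expect_setequal(unique(cal$stratum[cal$stratum_var == "p16"]),
                  c("positive", "negative"))
  sums <- tapply(cal$predicted,
                 interaction(cal$stratum_var, cal$stratum, cal$horizon,
                             drop = TRUE), sum)
  expect_equal(as.numeric(sums), rep(1, length(sums)), tolerance = 1e-6)
  obs_sums <- tapply(cal$observed,
                     interaction(cal$stratum_var, cal$stratum, cal$horizon,
                                 drop = TRUE), sum)
  expect_equal(as.numeric(obs_sums), rep(1, length(obs_sums)),
               tolerance = 1e-6)
  expect_true(all(cal$n_at_risk >= 0))
})

test_that("Cox-Snell residuals separate correct from misspecified models", {
  p <- reference_params()
  g <- generate_cohort(cohort_config(n = 3000, seed = 57,
                                     missingness = no_missingness), p)
  cs <- cox_snell_diagnostics(g$cohort, p)
  expect_true(cs$pass)
  expect_equal(cs$slope, 1, tolerance = 0.1)
  # zero follow-up gives a zero residual
  one <- g$cohort[1, ]
  one$followup_time <- 0
  one$death_time <- NA
  one$first_event <- "none"
  one$recurrence_time <- NA
  one$persistent <- FALSE
  r0 <- cox_snell_diagnostics(rbind(one, g$cohort[2:50, ]), p)
  expect_equal(r0$residuals$residual[1], 0, tolerance = 1e-8)
  # halved death hazards: clearly flagged
  bad <- p
  bad$c5$scale <- bad$c5$scale * 2^(1 / bad$c5$shape)
  bad$c6$scale <- bad$c6$scale * 2^(1 / bad$c6$shape)
  bad$c7$scale <- bad$c7$scale * 2^(1 / bad$c7$shape)
  bad$c8$scale <- bad$c8$scale * 2^(1 / bad$c8$shape)
  csb <- cox_snell_diagnostics(g$cohort, bad)
  expect_false(csb$pass)
  expect_gt(abs(csb$slope - 1), 0.2)
})

test_that("the full report carries coherent metrics", {
  p <- reference_params()
  g <- generate_cohort(cohort_config(n = 1500, seed = 59,
                                     missingness = no_missingness), p)
  v <- validation_report(g$cohort, p, strata = "p16")
  for (m in c("auc_os_5yr", "auc_efs_5yr", "c_index_os", "c_index_efs")) {
    expect_gte(v[[m]], 0.5)
    expect_lte(v[[m]], 1)
  }
  expect_s3_class(v$calibration, "data.frame")
  expect_true(v$cox_snell$pass)
})
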