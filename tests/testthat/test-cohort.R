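test_that("covariate marginals match the configured frequencies", {
  cfg <- cohort_config(n = 10000, seed = 42)
  set.seed(cfg$seed)
  covs <- generate_covariates(cfg)
  expect_equal(nrow(covs), 10000)
  expect_false(anyNA(covs))
  expect_equal(mean(covs$sex == "male"), 0.851, tolerance = 0.02)
  expect_equal(mean(covs$smoking == "current"), 0.321, tolerance = 0.06)
  expect_equal(mean(covs$p16 == "positive"), 0.828, tolerance = 0.02)
  expect_equal(median(covs$age), 58, tolerance = 0.02)
  expect_equal(median(exp(covs$log_mtv)), 13.6, tolerance = 0.05)
})

test_that("missingness masks fields at the configured rates", {
  cfg <- cohort_config(n = 10000, seed = 43)
  set.seed(cfg$seed)
  covs <- generate_covariates(cfg)
  masked <- impose_missingness(covs, cfg)
  expect_equal(mean(is.na(masked$p16)), 0.389, tolerance = 0.02)
  expect_equal(mean(is.na(masked$ace27)), 0.265, tolerance = 0.02)
  # imaging fields are missing jointly (same scan)
  expect_equal(is.na(masked$log_mtv), is.na(masked$rece))
  expect_equal(mean(is.na(masked$log_mtv)), 0.671, tolerance = 0.02)
  # truth retained for recovery tests
  expect_identical(attr(masked, "complete"), covs)
  # zero rates leave the table untouched
  cfg0 <- cohort_config(n = 100, seed = 1, missingness = no_missingness)
  set.seed(1)
  covs0 <- generate_covariates(cfg0)
  expect_identical(impose_missingness(covs0, cfg0)[names(covs0)], covs0)
})

test_that("cohort generation is reproducible under a fixed seed", {
  a <- generate_cohort(cohort_config(n = 300, seed = 7))
  b <- generate_cohort(cohort_config(n = 300, seed = 7))
  expect_identical(a, b)
  c2 <- generate_cohort(cohort_config(n = 300, seed = 8))
  expect_false(identical(a$cohort, c2$cohort))
})

test_that("trajectories respect the state topology", {
  p <- reference_params()
  # degenerate competing risks: recurrence hazards off, noncured forced
  pf <- p
  pf$c1$intercept <- -50; pf$c1$coef[] <- 0      # never persistent
  pf$c2$intercept <- 50; pf$c2$coef[] <- 0       # always noncured
  pf$c3$scale1 <- pf$c3$scale2 <- 1e9
  pf$c4$scale1 <- pf$c4$scale2 <- 1e9
  set.seed(5)
  tr <- simulate_trajectory(ref_patient(), pf, nsim = 500)
  expect_true(all(tr$true_state == 1))
  expect_true(all(tr$recurrence_type == "none"))
  expect_true(all(is.finite(tr$death_time)))

  # persistent patients never emit a recurrence
  pp <- p; pp$c1$intercept <- 50
  set.seed(6)
  tr6 <- simulate_trajectory(ref_patient(), pp, nsim = 500)
  expect_true(all(tr6$true_state == 6))
  expect_true(all(is.na(tr6$recurrence_time)))
})

test_that("latent-state frequencies track the analytic probabilities", {
  p <- reference_params()
  cfg <- cohort_config(n = 20000, seed = 13, missingness = no_missingness)
  g <- generate_cohort(cfg, p)
  pr <- colMeans(initial_state_probs(g$cohort, p))
  freq <- c(mean(g$truth$true_state == 6), mean(g$truth$true_state == 1),
            mean(g$truth$true_state == 2))
  expect_equal(freq, unname(pr[c("p_persistent", "p_noncured", "p_cured")]),
               tolerance = 0.01)
})

test_that("observation scheme applies the persistence labelling rules", {
  mk <- function(state, rec_type, rec_t, death_t)
    data.frame(true_state = state, recurrence_type = rec_type,
               recurrence_time = rec_t, death_time = death_t)
  # recurrence at 2.5 months is persistent disease, not a recurrence
  o1 <- apply_observation_scheme(mk(1, "lrr", 2.5, 40), censor_time = 100)
  expect_true(o1$persistent)
  expect_true(is.na(o1$recurrence_time))     # no recurrence transition
  expect_equal(o1$first_event, "death")      # the C6 outcome remains
  expect_equal(o1$death_time, 40)
  # death at 5 months with only 2 months of recurrence follow-up
  o2 <- apply_observation_scheme(mk(1, "none", NA, 5), censor_time = 100,
                                 recurrence_followup = 2)
  expect_true(o2$persistent)
  # same death with full recurrence follow-up is not persistent
  o3 <- apply_observation_scheme(mk(1, "none", NA, 5), censor_time = 100)
  expect_false(o3$persistent)
  expect_equal(o3$first_event, "death")
  # censored recurrence-free at 80 months gets the descriptive cured label
  o4 <- apply_observation_scheme(mk(1, "none", NA, 200), censor_time = 80)
  expect_true(o4$cured_label)
  expect_equal(o4$followup_time, 80)
  expect_true(is.na(o4$death_time))
  expect_equal(resolve_state_constraints(
    cbind(o4, id = "x")), c(1L, 2L))
  expect_error(apply_observation_scheme(mk(1, "none", NA, 10), -5),
               "positive")
})

test_that("generated cohorts satisfy the record invariants", {
  g <- generate_cohort(cohort_config(n = 840, seed = 3))
  co <- g$cohort
  expect_equal(nrow(co), 840)
  expect_equal(nrow(g$truth), 840)
  expect_false(any(co$persistent & co$first_event %in% c("lrr", "dm")))
  rec <- co$first_event %in% c("lrr", "dm")
  expect_true(all(co$recurrence_time[rec] <=
                    co$followup_time[rec] + 1e-12))
  expect_true(all(is.na(co$recurrence_time[!rec])))
  died <- !is.na(co$death_time)
  expect_equal(co$death_time[died], co$followup_time[died])
  expect_true(all(co$followup_time > 0))
  # truth sidecar aligns with the observed table
  expect_identical(g$truth$id, co$id)
})
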