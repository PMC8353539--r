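test_that("state constraints follow the observed outcome", {
  expect_equal(resolve_state_constraints(toy_record(persistent = TRUE)), 6L)
  expect_equal(resolve_state_constraints(
    toy_record(first_event = "lrr", recurrence_time = 14,
               followup_time = 40)), 1L)
  expect_equal(resolve_state_constraints(toy_record(followup_time = 30)),
               c(1L, 2L))
  expect_error(resolve_state_constraints(
    toy_record(persistent = TRUE, first_event = "dm",
               recurrence_time = 10)), "persistent")
})

test_that("log prior sums per-parameter densities and truncates on order", {
  p <- reference_params()
  pr <- prior_spec()
  lp <- log_prior(p, pr)
  # per-term oracle: independent normal densities on the flat vector
  theta <- curemsm:::flatten_params(p)
  ms <- curemsm:::prior_mean_sd(names(theta), pr)
  expect_equal(lp, sum(dnorm(theta, ms$mean, ms$sd, log = TRUE)))
  # violating the metastasis cN ordering gives -Inf
  bad <- p
  bad$c4$coef["cn_N3"] <- bad$c4$coef["cn_N2abc"] - 0.5
  expect_equal(log_prior(bad, pr), -Inf)
  bad2 <- p
  bad2$c4$coef["cn_N2abc"] <- -0.1   # below the reference at zero
  expect_equal(log_prior(bad2, pr), -Inf)
  # symmetry for unrestricted coefficients
  a <- p; a$c2$coef["anemia"] <- 1.3
  b <- p; b$c2$coef["anemia"] <- -1.3
  expect_equal(log_prior(a, pr), log_prior(b, pr))
})

test_that("latent-state draws match the exact two-branch posterior", {
  p <- reference_params()
  # no event information: posterior odds equal the prior odds
  p0 <- p
  p0$c3$scale1 <- p0$c3$scale2 <- 1e9
  p0$c4$scale1 <- p0$c4$scale2 <- 1e9
  co <- toy_record(followup_time = 50)
  pr <- initial_state_probs(ref_patient(), p0)
  want <- unname(pr[, "p_noncured"] / (pr[, "p_noncured"] + pr[, "p_cured"]))
  big <- co[rep(1, 20000), ]
  set.seed(31)
  st <- sample_latent_states(big, p0)
  expect_lt(abs(mean(st == 1) - want), 0.01)

  # exact enumeration oracle via the complete-data likelihood branches
  recs <- list(toy_record(followup_time = 20),
               toy_record(first_event = "death", death_time = 15,
                          followup_time = 15),
               toy_record(followup_time = 100,
                          covariates = ref_patient(p16 = "negative",
                                                   ct = "T3")))
  for (k in seq_along(recs)) {
    r <- recs[[k]]
    l1 <- complete_data_loglik(r, 1, p)
    l2 <- complete_data_loglik(r, 2, p)
    exact <- exp(l1) / (exp(l1) + exp(l2))
    big <- r[rep(1, 20000), ]
    set.seed(40 + k)
    st <- sample_latent_states(big, p)
    expect_lt(abs(mean(st == 1) - exact), 0.01)
  }

  # long recurrence-free follow-up under high hazard implies cure
  ph <- p
  ph$c3$scale1 <- ph$c3$scale2 <- 4
  r <- toy_record(followup_time = 110)
  set.seed(50)
  st <- sample_latent_states(r[rep(1, 2000), ], ph)
  expect_gt(mean(st == 2), 0.99)
})

test_that("chained-equations imputation preserves observed cells and marginals", {
  p <- reference_params()
  g <- generate_cohort(cohort_config(n = 20000, seed = 17,
    missingness = list(anemia = 0.3, ace27 = 0, smoking = 0, ct = 0,
                       cn = 0, p16 = 0.25, imaging = 0)), p)
  co <- g$cohort
  set.seed(1)
  completed <- impute_step(co)
  expect_false(anyNA(completed$anemia))
  expect_false(anyNA(completed$p16))
  obs <- !is.na(co$anemia)
  expect_identical(completed$anemia[obs], co$anemia[obs])
  # MCAR: imputed marginal should recover the hidden truth
  truth_marg <- mean(g$truth$anemia)
  expect_equal(mean(completed$anemia), truth_marg, tolerance = 0.02)
  expect_equal(mean(completed$p16 == "positive"),
               mean(g$truth$p16 == "positive"), tolerance = 0.02)
  # complete tables pass through unchanged
  full <- completed
  expect_identical(impute_step(full, full), full)
})

test_that("short MCMC runs recover strong effects and keep imputations", {
  p <- reference_params()
  g <- generate_cohort(cohort_config(n = 500, seed = 19,
    missingness = list(anemia = 0.15, ace27 = 0, smoking = 0, ct = 0,
                       cn = 0, p16 = 0.2, imaging = 0)), p)
  d <- run_mcmc(g$cohort, n_iter = 300, burnin = 100, seed = 2,
                impute_every = 10, n_imputations = 10)
  expect_s3_class(d, "msm_draws")
  expect_equal(nrow(d$draws), 200)
  expect_length(d$imputations, 10)
  expect_false(anyNA(d$imputations[[10]]$p16))
  # acceptance rates in a sane band after adaptation
  expect_true(all(d$acceptance > 0.05 & d$acceptance < 0.85))
  # defaults match the production run length
  expect_equal(formals(run_mcmc)$n_iter, 25000)
  expect_equal(formals(run_mcmc)$burnin, 10000)
})

test_that("identical seed and data give bitwise-identical draws", {
  g <- generate_cohort(cohort_config(n = 200, seed = 23))
  d1 <- run_mcmc(g$cohort, n_iter = 60, burnin = 20, seed = 9)
  d2 <- run_mcmc(g$cohort, n_iter = 60, burnin = 20, seed = 9)
  expect_identical(d1$draws, d2$draws)
  d3 <- run_mcmc(g$cohort, n_iter = 60, burnin = 20, seed = 10)
  expect_false(identical(d1$draws, d3$draws))
})

test_that("order restrictions hold in every retained draw", {
  g <- generate_cohort(cohort_config(n = 400, seed = 29,
                                     missingness = no_missingness))
  d <- run_mcmc(g$cohort, n_iter = 300, burnin = 100, seed = 3)
  n2 <- d$draws[, "c4.cn_N2abc"]
  n3 <- d$draws[, "c4.cn_N3"]
  expect_true(all(n2 >= 0))
  expect_true(all(n3 >= n2))
})

test_that("posterior summaries match sort-based quantiles", {
  g <- generate_cohort(cohort_config(n = 150, seed = 31))
  d <- run_mcmc(g$cohort, n_iter = 120, burnin = 40, seed = 4)
  s <- posterior_summary(d)
  expect_setequal(
    names(s), c("component", "term", "type", "mean", "lower", "upper",
                "ratio", "ratio_lower", "ratio_upper", "rhat"))
  j <- which(colnames(d$draws) == "c2.anemia")
  v <- sort(d$draws[, j])
  k <- s[s$component == "c2" & s$term == "anemia", ]
  expect_equal(k$mean, mean(v))
  expect_equal(k$lower, unname(quantile(v, 0.025)))
  expect_equal(k$upper, unname(quantile(v, 0.975)))
  expect_equal(k$ratio, exp(mean(v)))
  # a constant chain collapses to a point
  d0 <- d
  d0$draws[, j] <- 1.5
  s0 <- posterior_summary(d0)
  k0 <- s0[s0$component == "c2" & s0$term == "anemia", ]
  expect_equal(c(k0$mean, k0$lower, k0$upper), c(1.5, 1.5, 1.5))
  expect_error(posterior_summary(list(draws = d$draws[0, , drop = FALSE])),
               "no post-burn-in")
})
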