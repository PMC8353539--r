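# hand-rolled Weibull pieces for the oracle computations, written from the
# hazard definition rather than the package's closed forms
oracle_haz <- function(comp, t) {
  if (!is.null(comp$change_point)) {
    ifelse(t < comp$change_point,
           (comp$shape1 / comp$scale1) * (t / comp$scale1)^(comp$shape1 - 1),
           (comp$shape2 / comp$scale2) * (t / comp$scale2)^(comp$shape2 - 1))
  } else (comp$shape / comp$scale) * (t / comp$scale)^(comp$shape - 1)
}

# midpoint Riemann sum of the hazard: fine-grid approximation of H(t)
oracle_cumhaz <- function(comp, t, du = 0.001) {
  if (t <= 0) return(0)
  m <- floor(t / du)
  u <- seq(du / 2, by = du, length.out = m)
  rest <- t - m * du
  sum(oracle_haz(comp, u)) * du +
    if (rest > 0) oracle_haz(comp, m * du + rest / 2) * rest else 0
}

test_that("initial-state probabilities are a two-stage logistic mixture", {
  p0 <- reference_params()
  p0$c1$intercept <- 0; p0$c1$coef[] <- 0
  p0$c2$intercept <- 0; p0$c2$coef[] <- 0
  pr <- initial_state_probs(ref_patient(), p0)
  expect_equal(unname(pr[1, ]), c(0.5, 0.25, 0.25))

  # the rECE odds ratio acts on the C2 logit scale
  pi <- reference_params(imaging = TRUE)
  x0 <- ref_patient(); x1 <- ref_patient(rece = TRUE)
  q <- function(x) {
    pr <- initial_state_probs(x, pi)
    pr[, "p_noncured"] / (1 - pr[, "p_persistent"])
  }
  odds <- function(z) z / (1 - z)
  expect_equal(unname(odds(q(x1)) / odds(q(x0))), 3.67, tolerance = 1e-10)
})

test_that("initial-state probabilities sum to one for random parameters", {
  for (seed in 1:20) {
    p <- random_params(seed)
    pr <- initial_state_probs(random_covariates(seed + 50, n = 5), p)
    expect_true(all(pr >= 0 & pr <= 1))
    expect_equal(unname(rowSums(pr)), rep(1, 5), tolerance = 1e-12)
  }
  x <- ref_patient(); x$p16 <- NA
  expect_error(initial_state_probs(x, reference_params()), "imput")
})

test_that("cured censored patient reduces to log p_cured - H5", {
  p <- reference_params()
  rec <- toy_record(followup_time = 48)
  ll <- complete_data_loglik(rec, 2, p)
  pr <- initial_state_probs(ref_patient(), p)
  x5 <- encode_covariates(ref_patient(), component_specs()$c5)[1, ]
  expect_equal(ll, unname(log(pr[, "p_cured"]) -
                            transition_cumhaz("c5", 48, x5, p)))
})

test_that("post-recurrence death contributes a clock-reset density", {
  p <- reference_params()
  rec <- toy_record(first_event = "dm", recurrence_time = 12,
                    death_time = 20, followup_time = 20)
  ll <- complete_data_loglik(rec, 1, p)
  # manual composition: C2 mixture weight, competing risks to 12 months,
  # DM hazard at 12, then C8 density at 8 months on the reset clock
  x <- ref_patient()
  specs <- component_specs()
  pr <- initial_state_probs(x, p)
  enc <- function(id) encode_covariates(x, specs[[id]])[1, ]
  expected <- log(pr[, "p_noncured"]) -
    transition_cumhaz("c3", 12, enc("c3"), p) -
    transition_cumhaz("c4", 12, enc("c4"), p) -
    transition_cumhaz("c5", 12, enc("c5"), p) +
    log(transition_hazard("c4", 12, enc("c4"), p)) +
    log(transition_hazard("c8", 8, enc("c8"), p)) -
    transition_cumhaz("c8", 8, enc("c8"), p)
  expect_equal(ll, unname(expected))
  # the same record may not be assigned the cured state
  expect_error(complete_data_loglik(rec, 2, p), "allowed")
})

test_that("complete-data likelihood matches a fine-grid discrete-time oracle", {
  p <- random_params(7)
  specs <- component_specs()
  x <- ref_patient(p16 = "negative", ct = "T2", smoking = "current")
  enc <- function(id) encode_covariates(x, specs[[id]])[1, ]
  lp <- function(id) sum(enc(id) * p[[id]]$coef)

  # noncured, LRR at 4.2 months (before the change point), death at 9.5
  rec <- toy_record(first_event = "lrr", recurrence_time = 4.2,
                    death_time = 9.5, followup_time = 9.5, covariates = x)
  ll <- complete_data_loglik(rec, 1, p)
  pr <- initial_state_probs(x, p)
  H <- function(id, t) oracle_cumhaz(p[[id]], t) * exp(lp(id))
  h <- function(id, t) oracle_haz(p[[id]], t) * exp(lp(id))
  expected <- log(pr[, "p_noncured"]) -
    H("c3", 4.2) - H("c4", 4.2) - H("c5", 4.2) +
    log(h("c3", 4.2)) +
    log(h("c7", 9.5 - 4.2)) - H("c7", 9.5 - 4.2)
  expect_equal(ll, unname(expected), tolerance = 1e-6)

  # persistent patient censored alive
  recp <- toy_record(persistent = TRUE, followup_time = 30, covariates = x)
  expect_equal(complete_data_loglik(recp, 6, p),
               unname(log(pr[, "p_persistent"]) -
                        oracle_cumhaz(p$c6, 30)),
               tolerance = 1e-6)
})

test_that("observed-data likelihood marginalizes the allowed set", {
  p <- reference_params()
  known <- toy_record(first_event = "lrr", recurrence_time = 10,
                      death_time = NA, followup_time = 40)
  expect_equal(observed_data_loglik(known, p),
               complete_data_loglik(known, 1, p))
  amb <- toy_record(followup_time = 30)
  # direct two-branch summation oracle
  direct <- log(exp(complete_data_loglik(amb, 1, p)) +
                  exp(complete_data_loglik(amb, 2, p)))
  expect_equal(observed_data_loglik(amb, p), direct)
  amb_dead <- toy_record(first_event = "death", death_time = 25,
                         followup_time = 25)
  direct2 <- log(exp(complete_data_loglik(amb_dead, 1, p)) +
                   exp(complete_data_loglik(amb_dead, 2, p)))
  expect_equal(observed_data_loglik(amb_dead, p), direct2)
})

test_that("vanishing recurrence hazards collapse noncured onto cured", {
  # with C3 = C4 hazards ~ 0 the two branches differ only in the C2 weight
  p <- reference_params()
  p$c3$scale1 <- p$c3$scale2 <- 1e9
  p$c4$scale1 <- p$c4$scale2 <- 1e9
  rec <- toy_record(first_event = "death", death_time = 33,
                    followup_time = 33)
  pr <- initial_state_probs(ref_patient(), p)
  d <- complete_data_loglik(rec, 1, p) - complete_data_loglik(rec, 2, p)
  expect_equal(d, unname(log(pr[, "p_noncured"]) - log(pr[, "p_cured"])),
               tolerance = 1e-6)
})
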