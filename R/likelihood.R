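# Initial-state probabilities and the complete-/observed-data log-likelihood
# of the multistate cure model.
#
# Likelihood structure per patient, by initial state:
#   persistent (6): P(persistent) x C6 density (death) or survival (censor),
#     on the baseline clock;
#   cured (2):      P(cured) x C5 density/survival -- no recurrence hazard;
#   noncured (1):   P(noncured) x competing-risk factor
#     exp(-H3 - H4 - H5)(t1) with the cause-specific hazard at the first
#     event, then, after a recurrence, a C7 (LRR) or C8 (DM) density or
#     survival on a clock reset at recurrence.
# Patients who are nonpersistent and recurrence-free have latent initial
# state in {1, 2}; the observed-data likelihood sums the two branches.

#' Initial-state probabilities
#'
#' Computes the probabilities of the three initial states from the two
#' logistic component models: `p_persistent = expit(eta1)` (C1),
#' `p_noncured = (1 - p_persistent) * expit(eta2)` (C2), and
#' `p_cured` as the remainder. The three sum to one.
#'
#' @param newdata Data frame of raw covariates (see [encode_covariates()]);
#'   the C1/C2 covariate subsets must be complete (impute first if needed).
#' @param params An [msm_params] object.
#' @return Matrix with columns `p_persistent`, `p_noncured`, `p_cured`, one
#'   row per row of `newdata`.
#' @export
initial_state_probs <- function(newdata, params) {
  specs <- params_specs(params)
  std <- params_std(params)
  X1 <- encode_covariates(newdata, specs$c1, std)
  X2 <- encode_covariates(newdata, specs$c2, std)
  if (anyNA(X1) || anyNA(X2))
    abort(paste("missing covariate values in the C1/C2 subsets;",
                "impute before calling initial_state_probs"))
  p6 <- expit(params$c1$intercept + drop(X1 %*% params$c1$coef))
  q  <- expit(params$c2$intercept + drop(X2 %*% params$c2$coef))
  cbind(p_persistent = p6, p_noncured = (1 - p6) * q,
        p_cured = (1 - p6) * (1 - q))
}

#' Resolve initial-state constraints from observed outcomes
#'
#' The initial state is fixed but possibly unknown: persistent disease pins
#' it to state 6 and an observed recurrence to state 1 (only noncured
#' patients can recur), while a nonpersistent, recurrence-free patient may
#' be either noncured (1) or cured (2) regardless of follow-up length.
#'
#' @param record One patient row (list or single-row data frame) with
#'   outcome fields `persistent`, `first_event`.
#' @return Integer vector of allowed initial states.
#' @export
resolve_state_constraints <- function(record) {
  record <- as.list(record)
  if (isTRUE(record$persistent)) {
    if (record$first_event %in% c("lrr", "dm"))
      abort("record %s is persistent but carries a recurrence event",
            record$id %||% "?")
    return(6L)
  }
  if (record$first_event %in% c("lrr", "dm")) return(1L)
  c(1L, 2L)
}

record_design <- function(record, params) {
  specs <- params_specs(params)
  std <- params_std(params)
  lapply(specs, function(s)
    drop(encode_covariates(as.data.frame(as.list(record)[COVARIATE_FIELDS],
                                         optional = TRUE),
                           s, std)))
}

haz_terms <- function(params, id, x, time, event) {
  comp <- params[[id]]
  lp <- if (length(comp$coef)) sum(x * comp$coef) else 0
  H <- baseline_cumhaz(comp, time) * exp(lp)
  ll <- -H
  if (event) ll <- ll + log(baseline_haz(comp, max(time, 1e-10))) + lp
  ll
}

#' Complete-data log-likelihood of one patient
#'
#' Log-likelihood of a patient record given an assigned initial state, the
#' quantity targeted by the latent-state data augmentation.
#'
#' @param record Patient row with covariates and outcome fields
#'   (`persistent`, `first_event`, `recurrence_time`, `death_time`,
#'   `followup_time`); covariates used by the model must be complete.
#' @param assigned_state 1 (noncured), 2 (cured) or 6 (persistent); must lie
#'   in the record's allowed set.
#' @param params An [msm_params] object.
#' @return Log-likelihood (scalar).
#' @export
complete_data_loglik <- function(record, assigned_state, params) {
  record <- as.list(record)
  allowed <- resolve_state_constraints(record)
  if (!(assigned_state %in% allowed))
    abort("assigned state %s not in allowed set {%s}", assigned_state,
          toString(allowed))
  X <- record_design(record, params)
  pr <- initial_state_probs(
    as.data.frame(record[COVARIATE_FIELDS], optional = TRUE), params)
  died <- !is.na(record$death_time)
  t_end <- if (died) record$death_time else record$followup_time

  if (assigned_state == 6)
    return(unname(log(pr[, "p_persistent"]) +
                    haz_terms(params, "c6", numeric(), t_end, died)))
  if (assigned_state == 2)
    return(unname(log(pr[, "p_cured"]) +
                    haz_terms(params, "c5", X$c5, t_end, died)))

  # noncured: competing risks until the first event, then clock-reset death
  recur <- record$first_event %in% c("lrr", "dm")
  t1 <- if (recur) record$recurrence_time else t_end
  ll <- log(pr[, "p_noncured"]) +
    haz_terms(params, "c3", X$c3, t1, identical(record$first_event, "lrr")) +
    haz_terms(params, "c4", X$c4, t1, identical(record$first_event, "dm")) +
    haz_terms(params, "c5", X$c5, t1,
              identical(record$first_event, "death"))
  if (recur) {
    t2 <- t_end - record$recurrence_time
    id2 <- if (record$first_event == "lrr") "c7" else "c8"
    ll <- ll + haz_terms(params, id2, X[[id2]], max(t2, 1e-10), died)
  }
  unname(ll)
}

#' Observed-data log-likelihood of one patient
#'
#' Marginalizes [complete_data_loglik] over the record's allowed initial
#' states (log-sum-exp); reduces to the complete-data value when the state
#' is known.
#'
#' @inheritParams complete_data_loglik
#' @return Log-likelihood (scalar).
#' @export
observed_data_loglik <- function(record, params) {
  allowed <- resolve_state_constraints(record)
  logsumexp(vapply(allowed, function(s)
    complete_data_loglik(record, s, params), numeric(1)))
}

# --- vectorized cohort machinery (used by the sampler and predictions) ---

# Precompute design matrices, times and event indicators for a cohort.
# Design rows for records with missing covariates contain NAs until the
# imputation step fills them in.
prep_msm_data <- function(cohort, params) {
  specs <- params_specs(params)
  std <- params_std(params)
  n <- nrow(cohort)
  died <- !is.na(cohort$death_time)
  t_end <- ifelse(died, cohort$death_time, cohort$followup_time)
  recur <- cohort$first_event %in% c("lrr", "dm")
  t1 <- ifelse(recur, cohort$recurrence_time, t_end)
  list(
    n = n,
    persistent = cohort$persistent,
    died = died,
    ev = cohort$first_event,
    t_end = t_end,
    t1 = t1,                       # first-event/censor time from baseline
    t2 = pmax(t_end - ifelse(recur, cohort$recurrence_time, 0), 1e-10),
    recur = recur,
    known1 = !cohort$persistent & recur,
    ambiguous = !cohort$persistent & !recur,
    X = lapply(specs, function(s) encode_covariates(cohort, s, std))
  )
}

ll_logistic <- function(intercept, coef, X, y, rows) {
  eta <- intercept + if (length(coef)) drop(X[rows, , drop = FALSE] %*% coef)
                     else 0
  sum(y[rows] * eta - log1p(exp(eta)))
}

ll_hazard <- function(comp, X, time, event, rows) {
  lp <- if (length(comp$coef)) drop(X[rows, , drop = FALSE] %*% comp$coef)
        else rep(0, length(rows))
  tt <- time[rows]
  ee <- event[rows]
  ll <- -sum(baseline_cumhaz(comp, tt) * exp(lp))
  if (any(ee))
    ll <- ll + sum(log(baseline_haz(comp, pmax(tt[ee], 1e-10)))) +
      sum(lp[ee])
  ll
}

# complete-data log-likelihood factor of one component given assigned states
component_loglik <- function(id, params, dat, state) {
  switch(id,
    c1 = ll_logistic(params$c1$intercept, params$c1$coef, dat$X$c1,
                     dat$persistent, seq_len(dat$n)),
    c2 = ll_logistic(params$c2$intercept, params$c2$coef, dat$X$c2,
                     state == 1, which(!dat$persistent)),
    c3 = ll_hazard(params$c3, dat$X$c3, dat$t1, dat$ev == "lrr",
                   which(state == 1)),
    c4 = ll_hazard(params$c4, dat$X$c4, dat$t1, dat$ev == "dm",
                   which(state == 1)),
    c5 = ll_hazard(params$c5, dat$X$c5, dat$t1,
                   dat$ev == "death" & !dat$recur,
                   which(!dat$persistent)),
    c6 = ll_hazard(params$c6, dat$X$c6, dat$t_end, dat$died,
                   which(dat$persistent)),
    c7 = ll_hazard(params$c7, dat$X$c7, dat$t2, dat$died,
                   which(dat$ev == "lrr")),
    c8 = ll_hazard(params$c8, dat$X$c8, dat$t2, dat$died,
                   which(dat$ev == "dm")),
    abort("unknown component '%s'", id))
}

complete_loglik_cohort <- function(params, dat, state) {
  sum(vapply(paste0("c", 1:8), component_loglik, numeric(1),
             params = params, dat = dat, state = state))
}

# --- marginal (collapsed) likelihood factors --------------------------
#
# For the ambiguous records the initial state can be summed out in closed
# form: their joint contribution to C2/C3/C4 is
#   prod_amb [ q_i exp(-(H3_i + H4_i)(t_i)) + (1 - q_i) ],
# with the common C5 factor cancelling between the two branches. The
# collapsed factor for each of C2, C3, C4 is its known-state term plus this
# shared mixture term, which mixes much faster than updating against
# augmented state draws.

mixture_term <- function(q, H3, H4) sum(log(q * exp(-(H3 + H4)) + 1 - q))

# cached per-ambiguous-record quantities under the current parameters
marg_cache <- function(params, dat) {
  amb <- which(dat$ambiguous)
  lin <- function(id) {
    comp <- params[[id]]
    if (!length(comp$coef)) rep(0, length(amb))
    else drop(dat$X[[id]][amb, , drop = FALSE] %*% comp$coef)
  }
  list(amb = amb,
       q = expit(params$c2$intercept + lin("c2")),
       H3 = baseline_cumhaz(params$c3, dat$t1[amb]) * exp(lin("c3")),
       H4 = baseline_cumhaz(params$c4, dat$t1[amb]) * exp(lin("c4")))
}

# collapsed factor for one of c2/c3/c4 given candidate parameters. Returns
# the known-state term `kn`, the shared mixture term `M` under the
# candidate, their sum `val`, and the cache piece to store on acceptance.
marg_loglik <- function(id, params, dat, cache) {
  known <- which(dat$known1)
  if (id == "c2") {
    eta_k <- params$c2$intercept +
      if (length(params$c2$coef))
        drop(dat$X$c2[known, , drop = FALSE] %*% params$c2$coef) else 0
    eta_a <- params$c2$intercept +
      if (length(params$c2$coef))
        drop(dat$X$c2[cache$amb, , drop = FALSE] %*% params$c2$coef) else 0
    q <- expit(eta_a)
    kn <- sum(eta_k - log1p(exp(eta_k)))
    M <- mixture_term(q, cache$H3, cache$H4)
    list(kn = kn, M = M, val = kn + M, piece = q)
  } else {
    comp <- params[[id]]
    lp_a <- if (length(comp$coef))
      drop(dat$X[[id]][cache$amb, , drop = FALSE] %*% comp$coef) else 0
    H <- baseline_cumhaz(comp, dat$t1[cache$amb]) * exp(lp_a)
    ev <- if (id == "c3") dat$ev == "lrr" else dat$ev == "dm"
    kn <- ll_hazard(comp, dat$X[[id]], dat$t1, ev, known)
    M <- if (id == "c3") mixture_term(cache$q, H, cache$H4)
         else mixture_term(cache$q, cache$H3, H)
    list(kn = kn, M = M, val = kn + M, piece = H)
  }
}

# P(state = 1 | data, params) for the ambiguous (nonpersistent,
# recurrence-free) records. For these records the C5 factor is common to
# both branches, so the posterior odds reduce to
#   p1 * exp(-(H3 + H4)(t1)) : p2.
state1_posterior <- function(params, dat, rows = which(dat$ambiguous)) {
  lp3 <- if (length(params$c3$coef))
    drop(dat$X$c3[rows, , drop = FALSE] %*% params$c3$coef) else 0
  lp4 <- if (length(params$c4$coef))
    drop(dat$X$c4[rows, , drop = FALSE] %*% params$c4$coef) else 0
  H34 <- baseline_cumhaz(params$c3, dat$t1[rows]) * exp(lp3) +
         baseline_cumhaz(params$c4, dat$t1[rows]) * exp(lp4)
  eta2 <- params$c2$intercept +
    if (length(params$c2$coef))
      drop(dat$X$c2[rows, , drop = FALSE] %*% params$c2$coef) else 0
  q <- expit(eta2)                    # P(noncured | nonpersistent)
  a <- q * exp(-H34)
  a / (a + (1 - q))
}
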