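# Synthetic cohort generation: covariates with realistic marginals and
# missingness, latent initial states and event times drawn from the
# multistate model, and an observation scheme (administrative censoring,
# persistent-disease labelling) that produces analysis-ready records plus a
# hidden truth sidecar for recovery tests.

#' Cohort generator configuration
#'
#' Defaults emulate the training cohort: 85.1% male, median age 58 years,
#' smoking 33.0/34.5/31.9% never/former/current, 82.8% p16-positive among
#' known, anemia 17.3%, median metabolic tumor volume 13.6 mL, rECE 19.6%
#' among imaged; missingness fractions from the cohort's "unknown" rows
#' (p16 38.9%, imaging 67.1% with MTV and rECE missing jointly, ACE27 26.5%,
#' cN 12.7%, anemia 14.0%, smoking 0.6%, cT 0.4%). Censoring is
#' administrative: uniform accrual over `accrual_months` with a data lock at
#' `lock_months` after the start of accrual, giving potential follow-up
#' between `lock_months - accrual_months` and `lock_months` (defaults mirror
#' accrual over 163 months and a lock 194 months after it opened).
#'
#' @param n Number of patients.
#' @param seed Integer seed; all randomness in [generate_cohort()] flows
#'   from it.
#' @param marginals Named list overriding covariate marginal settings (see
#'   defaults in the function body).
#' @param missingness Named list of per-field missingness probabilities;
#'   `imaging` applies jointly to `log_mtv` and `rece`.
#' @param accrual_months,lock_months Censoring window (months).
#' @param persistence_window_months Recurrence at or before this time is
#'   labelled persistent disease (the ~12-week posttreatment evaluation).
#' @param followup_threshold_months Patients with less recurrence follow-up
#'   than this who die within `early_death_months` are labelled persistent.
#' @param early_death_months See above; default 6.
#' @param smoking_p16_log_or Optional pairwise dependence: log odds ratio
#'   tilting p16-negative status for current smokers (0 = independent
#'   marginals, the default).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n = 840, seed = 1,
                          marginals = list(),
                          missingness = list(),
                          accrual_months = 163, lock_months = 194,
                          persistence_window_months = 3,
                          followup_threshold_months = 3,
                          early_death_months = 6,
                          smoking_p16_log_or = 0) {
  m <- utils::modifyList(list(
    p_male = 0.851,
    age_mean = 58, age_sd = 9.2,
    p_anemia = 0.173,
    ace27 = c(none = 0.332, mild = 0.417, moderate = 0.180, severe = 0.071),
    smoking = c(never = 0.332, former = 0.347, current = 0.321),
    p_p16_positive = 0.828,
    ct = c(T1 = 0.226, T2 = 0.333, T3 = 0.163, T4 = 0.278),
    cn = c(N0 = 0.136, N1 = 0.518, N2abc = 0.240, N3 = 0.106),
    mtv_meanlog = log(13.6), mtv_sdlog = 0.67,
    p_rece = 0.196), marginals)
  miss <- utils::modifyList(list(
    age = 0, sex = 0, anemia = 0.140, ace27 = 0.265, smoking = 0.006,
    ct = 0.004, cn = 0.127, p16 = 0.389, imaging = 0.671), missingness)
  stopifnot(n >= 1, all(unlist(miss) >= 0), all(unlist(miss) <= 1),
            lock_months > accrual_months, accrual_months >= 0)
  for (nm in c("ace27", "smoking", "ct", "cn"))
    m[[nm]] <- m[[nm]] / sum(m[[nm]])
  structure(list(n = as.integer(n), seed = as.integer(seed), marginals = m,
                 missingness = miss, accrual_months = accrual_months,
                 lock_months = lock_months,
                 persistence_window_months = persistence_window_months,
                 followup_threshold_months = followup_threshold_months,
                 early_death_months = early_death_months,
                 smoking_p16_log_or = smoking_p16_log_or),
            class = "cohort_config")
}

sample_cat <- function(n, probs) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

#' Generate complete baseline covariates
#'
#' Draws `config$n` patients with complete covariates from the configured
#' marginals (independent by default; an optional smoking-p16 association
#' can be switched on via `smoking_p16_log_or`).
#'
#' @param config A [cohort_config()].
#' @return Data frame with columns `id`, `age`, `sex`, `ace27`, `smoking`,
#'   `anemia`, `p16`, `ct`, `cn`, `log_mtv`, `rece`.
#' @export
generate_covariates <- function(config) {
  m <- config$marginals
  n <- config$n
  smoking <- factor(sample_cat(n, m$smoking),
                    levels = COVARIATE_LEVELS$smoking)
  # optional tilt: current smokers more often p16-negative
  eta_p16 <- stats::qlogis(m$p_p16_positive) -
    config$smoking_p16_log_or * (smoking == "current")
  data.frame(
    id = sprintf("P%05d", seq_len(n)),
    age = round(stats::rnorm(n, m$age_mean, m$age_sd), 1),
    sex = ifelse(stats::runif(n) < m$p_male, "male", "female"),
    ace27 = sample_cat(n, m$ace27),
    smoking = as.character(smoking),
    anemia = stats::runif(n) < m$p_anemia,
    p16 = ifelse(stats::runif(n) < expit(eta_p16), "positive", "negative"),
    ct = sample_cat(n, m$ct),
    cn = sample_cat(n, m$cn),
    log_mtv = stats::rnorm(n, m$mtv_meanlog, m$mtv_sdlog),
    rece = stats::runif(n) < m$p_rece,
    stringsAsFactors = FALSE)
}

#' Mask covariates missing-completely-at-random
#'
#' Sets covariate cells to `NA` independently at the configured per-field
#' rates; the imaging fields (`log_mtv`, `rece`) are masked jointly, since
#' both come from the same pretreatment scan. The complete table is retained
#' in the `"complete"` attribute for recovery tests.
#'
#' @param covariates Complete covariate table from [generate_covariates()].
#' @param config A [cohort_config()].
#' @return The masked table, with the original as `attr(, "complete")`.
#' @export
impose_missingness <- function(covariates, config) {
  miss <- config$missingness
  out <- covariates
  n <- nrow(out)
  for (f in c("age", "sex", "anemia", "ace27", "smoking", "ct", "cn",
              "p16"))
    if (miss[[f]] > 0) out[[f]][stats::runif(n) < miss[[f]]] <- NA
  if (miss$imaging > 0) {
    no_scan <- stats::runif(n) < miss$imaging
    out$log_mtv[no_scan] <- NA
    out$rece[no_scan] <- NA
  }
  attr(out, "complete") <- covariates
  out
}

# vectorized trajectory simulation; `newdata` must be complete
sim_trajectories <- function(newdata, params, nsim = nrow(newdata)) {
  if (nrow(newdata) == 1 && nsim > 1)
    newdata <- newdata[rep(1, nsim), , drop = FALSE]
  n <- nrow(newdata)
  specs <- params_specs(params)
  std <- params_std(params)
  pr <- initial_state_probs(newdata, params)
  lp <- function(id) {
    comp <- params[[id]]
    if (!length(comp$coef)) return(rep(0, n))
    drop(encode_covariates(newdata, specs[[id]], std) %*% comp$coef)
  }
  draw_time <- function(id, rows, lpv) {
    E <- stats::rexp(length(rows))
    baseline_cumhaz_inv(params[[id]], E / exp(lpv[rows]))
  }
  u <- stats::runif(n)
  state <- ifelse(u < pr[, "p_persistent"], 6L,
                  ifelse(u < pr[, "p_persistent"] + pr[, "p_noncured"],
                         1L, 2L))
  rec_type <- rep("none", n)
  rec_time <- rep(NA_real_, n)
  death <- rep(NA_real_, n)

  i6 <- which(state == 6L)
  death[i6] <- draw_time("c6", i6, rep(0, n))
  i2 <- which(state == 2L)
  lp5 <- lp("c5")
  death[i2] <- draw_time("c5", i2, lp5)
  i1 <- which(state == 1L)
  if (length(i1)) {
    t3 <- draw_time("c3", i1, lp("c3"))
    t4 <- draw_time("c4", i1, lp("c4"))
    t5 <- draw_time("c5", i1, lp5)
    first <- pmin(t3, t4, t5)
    kind <- ifelse(t3 == first, "lrr", ifelse(t4 == first, "dm", "death"))
    death[i1[kind == "death"]] <- first[kind == "death"]
    for (k in c("lrr", "dm")) {
      ii <- i1[kind == k]
      if (!length(ii)) next
      rec_type[ii] <- k
      rec_time[ii] <- first[kind == k]
      id2 <- if (k == "lrr") "c7" else "c8"
      death[ii] <- rec_time[ii] + draw_time(id2, ii, lp(id2))
    }
  }
  data.frame(true_state = state, recurrence_type = rec_type,
             recurrence_time = rec_time, death_time = death)
}

#' Simulate uncensored disease trajectories
#'
#' Draws the latent initial state from the C1/C2 probabilities, then event
#' times from the transition models: persistent patients die via C6, cured
#' patients via C5, and noncured patients experience the first of
#' locoregional recurrence (C3), distant metastasis (C4) or death (C5) --
#' piecewise hazards are inverted exactly with the 6-month split handled
#' analytically -- followed by post-recurrence death from C7 or C8 on a
#' clock reset at recurrence.
#'
#' @param newdata Complete covariate data frame (one or more rows).
#' @param params An [msm_params] object.
#' @param nsim If `newdata` has a single row, the number of independent
#'   trajectories to draw from it.
#' @return Data frame with `true_state` (1, 2 or 6), `recurrence_type`
#'   (`"none"`, `"lrr"`, `"dm"`), `recurrence_time` and `death_time`
#'   (months from baseline; recurrence time `NA` when none occurs).
#' @export
simulate_trajectory <- function(newdata, params, nsim = nrow(newdata)) {
  sim_trajectories(as.data.frame(newdata), params, nsim)
}

#' Apply the observation scheme to uncensored trajectories
#'
#' Administratively censors each trajectory and applies the study's
#' persistent-disease labelling: a recurrence detected at or before the
#' posttreatment evaluation window (default 3 months) is recorded as
#' persistent disease rather than a recurrence, as is an early death
#' (within 6 months) with under 3 months of recurrence follow-up. Patients
#' reaching 72 recurrence-free months get the descriptive cured label.
#'
#' @param truth Data frame from [simulate_trajectory()] (plus optionally a
#'   `true_state` column).
#' @param censor_time Administrative censoring time(s), months (recycled).
#' @param recurrence_followup Optional recurrence-specific follow-up time(s)
#'   (months); defaults to follow-up for death.
#' @param config A [cohort_config()] supplying the labelling windows.
#' @return Data frame of observed outcome fields: `persistent`,
#'   `first_event`, `recurrence_time`, `death_time`, `followup_time`,
#'   `cured_label`.
#' @export
apply_observation_scheme <- function(truth, censor_time,
                                     recurrence_followup = NULL,
                                     config = cohort_config()) {
  if (any(censor_time <= 0)) abort("censor_time must be positive")
  n <- nrow(truth)
  censor <- rep_len(censor_time, n)
  died <- truth$death_time <= censor
  death_obs <- ifelse(died, truth$death_time, NA_real_)
  followup <- pmin(truth$death_time, censor)
  rec_seen <- !is.na(truth$recurrence_time) &
    truth$recurrence_time <= followup
  rec_fu <- if (is.null(recurrence_followup)) followup
            else pmin(rep_len(recurrence_followup, n), followup)

  persistent <- (truth$true_state %||% rep(NA, n)) == 6
  persistent[is.na(persistent)] <- FALSE
  # early recurrence is persistent disease by definition
  persistent <- persistent |
    (rec_seen & truth$recurrence_time <= config$persistence_window_months)
  # early death with too little recurrence follow-up
  persistent <- persistent |
    (!rec_seen & died & death_obs <= config$early_death_months &
       rec_fu < config$followup_threshold_months)

  rec_kept <- rec_seen & !persistent
  first_event <- ifelse(rec_kept, truth$recurrence_type,
                        ifelse(died, "death", "none"))
  data.frame(
    persistent = persistent,
    first_event = first_event,
    recurrence_time = ifelse(rec_kept, truth$recurrence_time, NA_real_),
    death_time = death_obs,
    followup_time = followup,
    cured_label = !persistent & !rec_kept & rec_fu >= 72)
}

#' Generate a complete synthetic cohort
#'
#' End-to-end generation: covariates, missingness masks, latent states and
#' event times from the model, administrative censoring and outcome
#' labelling. All randomness flows from `config$seed`, so the cohort is
#' reproducible bit for bit.
#'
#' @param config A [cohort_config()].
#' @param params Generating [msm_params]; defaults to [reference_params()].
#' @return List with `cohort` (observed records: covariates with `NA` for
#'   missing cells plus outcome columns) and `truth` (hidden sidecar:
#'   complete covariates, latent state, uncensored event times and the
#'   censoring time of each patient).
#' @export
generate_cohort <- function(config = cohort_config(),
                            params = reference_params()) {
  set.seed(config$seed)
  complete <- generate_covariates(config)
  covs <- impose_missingness(complete, config)
  truth <- sim_trajectories(complete, params)
  entry <- stats::runif(config$n, 0, config$accrual_months)
  censor <- config$lock_months - entry
  obs <- apply_observation_scheme(truth, censor, config = config)
  cohort <- cbind(covs, obs)
  sidecar <- cbind(id = complete$id, truth, censor_time = censor,
                   complete[-1])
  attr(cohort, "complete") <- NULL
  list(cohort = cohort, truth = sidecar)
}
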