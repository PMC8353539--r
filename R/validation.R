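# Evaluation battery: time-dependent AUC with inverse-probability-of-
# censoring weights, Harrell's concordance index, calibration of predicted
# state-occupancy categories against Aalen-Johansen / Kaplan-Meier
# estimates, and Cox-Snell goodness-of-fit diagnostics.

#' Time-dependent AUC under censoring
#'
#' Cumulative-case / dynamic-control AUC at a horizon: cases are patients
#' with an event at or before the horizon, controls those still event-free
#' at the horizon. Inverse-probability-of-censoring weights from a marginal
#' Kaplan-Meier estimate of the censoring distribution make the estimator
#' consistent under independent censoring; with no censoring before the
#' horizon it reduces to the Mann-Whitney statistic.
#'
#' @param risk Per-patient risk score (higher = more likely to have the
#'   event by the horizon).
#' @param time Event or censoring time (months).
#' @param event Event indicator (1/TRUE = event).
#' @param horizon Evaluation horizon in months (default 60).
#' @return AUC in `[0, 1]`, with the weighting scheme recorded in the
#'   `"estimator"` attribute.
#' @export
time_dependent_auc <- function(risk, time, event, horizon = 60) {
  event <- as.numeric(event)
  stopifnot(length(risk) == length(time), length(time) == length(event))
  cens_fit <- survival::survfit(
    survival::Surv(time, 1 - event) ~ 1)
  G <- stats::stepfun(cens_fit$time, c(1, cens_fit$surv), right = FALSE)
  # left limit of G at t: value just before t
  Gminus <- function(t) G(t - 1e-9)
  is_case <- time <= horizon & event == 1
  is_ctrl <- time > horizon
  if (!any(is_case) || !any(is_ctrl))
    abort("AUC undefined: no %s by the horizon",
          if (!any(is_case)) "cases" else "controls")
  w_case <- 1 / pmax(Gminus(time[is_case]), 1e-8)
  w_ctrl <- rep(1 / pmax(Gminus(horizon), 1e-8), sum(is_ctrl))
  r_case <- risk[is_case]
  r_ctrl <- risk[is_ctrl]
  u <- sort(unique(c(r_case, r_ctrl)))
  cw <- numeric(length(u))
  agg <- rowsum(w_ctrl, match(r_ctrl, u))
  cw[as.integer(rownames(agg))] <- agg
  below <- c(0, cumsum(cw))[match(r_case, u)]
  ties <- cw[match(r_case, u)]
  auc <- sum(w_case * (below + 0.5 * ties)) /
    (sum(w_case) * sum(w_ctrl))
  structure(auc, estimator = "IPCW (marginal KM of censoring)")
}

#' Harrell's concordance index
#'
#' Fraction of usable pairs (one patient with an observed event strictly
#' before the other's last known event-free time) in which the earlier
#' event carries the higher risk score; risk ties count one half.
#'
#' @inheritParams time_dependent_auc
#' @return Concordance in `[0, 1]`.
#' @export
concordance_index <- function(risk, time, event) {
  event <- as.logical(event)
  idx <- which(event)
  if (!length(idx)) abort("no events: concordance undefined")
  num <- den <- 0
  for (i in idx) {
    usable <- time > time[i]
    if (!any(usable)) next
    den <- den + sum(usable)
    num <- num + sum(risk[i] > risk[usable]) +
      0.5 * sum(risk[i] == risk[usable])
  }
  if (den == 0) abort("no usable pairs: concordance undefined")
  num / den
}

# observed four-category occupancy in a cohort subset: persistent patients
# occupy category 3 from time zero; among the rest, Aalen-Johansen
# cumulative incidence of the competing first events
observed_categories <- function(cohort, horizons) {
  n <- nrow(cohort)
  w6 <- mean(cohort$persistent)
  np <- cohort[!cohort$persistent, , drop = FALSE]
  died <- !is.na(np$death_time)
  t_end <- ifelse(died, np$death_time, np$followup_time)
  recur <- np$first_event %in% c("lrr", "dm")
  t1 <- ifelse(recur, np$recurrence_time, t_end)
  ev <- factor(ifelse(np$first_event == "none", "censor", np$first_event),
               levels = c("censor", "lrr", "dm", "death"))
  fit <- survival::survfit(survival::Surv(t1, ev) ~ 1)
  sm <- summary(fit, times = pmin(horizons, max(fit$time)), extend = TRUE)
  P <- sm$pstate
  colnames(P) <- sm$states
  data.frame(
    horizon = horizons,
    n = n,
    n_at_risk = sm$n.risk[, 1],
    no_event = (1 - w6) * P[, "(s0)"],
    dm_first = (1 - w6) * P[, "dm"],
    lrr_or_persistent = w6 + (1 - w6) * P[, "lrr"],
    death_norec = (1 - w6) * P[, "death"])
}

#' Calibration of predicted categories by strata
#'
#' Within strata defined by a covariate label (e.g. cT classification or
#' p16 status), compares the mean predicted four-category occupancy at the
#' requested horizons against nonparametric estimates: Aalen-Johansen
#' cumulative incidence for the competing first-event categories and the
#' Kaplan-Meier event-free estimate for the no-event category, with the
#' persistent-disease fraction entering category 3 from time zero.
#'
#' @param cohort Cohort data frame with complete covariates (or supply
#'   `predictions`).
#' @param params An [msm_params] object.
#' @param strata Covariate column(s) to stratify on (default `"ct"`); use
#'   `NULL` for a single overall stratum.
#' @param horizons Horizons in months.
#' @param predictions Optional precomputed array from the package's
#'   cohort-level occupancy computation (n x 8 x horizons).
#' @param step Quadrature step for the predictions.
#' @return Long data frame: `stratum_var`, `stratum`, `horizon`, `n`,
#'   `n_at_risk`, `category`, `observed`, `predicted`.
#' @export
calibration_by_strata <- function(cohort, params, strata = "ct",
                                  horizons = c(12, 36, 60),
                                  predictions = NULL, step = 0.1) {
  if (is.null(predictions))
    predictions <- cohort_occupancy(cohort, params, horizons, step)
  labels <- if (is.null(strata)) list(all = rep("all", nrow(cohort)))
            else lapply(stats::setNames(strata, strata),
                        function(v) cohort[[v]])
  out <- list()
  for (v in names(labels)) {
    lab <- labels[[v]]
    for (s in stats::na.omit(unique(lab))) {
      rows <- which(!is.na(lab) & lab == s)
      if (!length(rows)) abort("empty stratum %s=%s", v, s)
      obs <- observed_categories(cohort[rows, , drop = FALSE], horizons)
      pred <- apply(predictions[rows, , , drop = FALSE], 3, function(f)
        colMeans(fine_to_report(f)))
      for (k in seq_along(horizons))
        out[[length(out) + 1]] <- data.frame(
          stratum_var = v, stratum = as.character(s),
          horizon = horizons[k], n = obs$n[k],
          n_at_risk = obs$n_at_risk[k],
          category = REPORT_CATEGORIES,
          observed = as.numeric(obs[k, REPORT_CATEGORIES]),
          predicted = pred[, k])
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Cox-Snell goodness-of-fit diagnostics
#'
#' Computes each patient's Cox-Snell residual for overall survival — the
#' model-implied marginal cumulative hazard of death at the observed death
#' or censoring time, carrying the censoring indicator — and compares the
#' Kaplan-Meier curve of the residuals with the unit-exponential survival
#' `exp(-r)` expected under a correctly specified model. The check
#' evaluates deciles of the residual distribution: a point passes when the
#' KM estimate lies within its pointwise 95% Greenwood band of `exp(-r)`,
#' and the overall flag requires at least 90% of points passing. The slope
#' of the residuals' cumulative hazard against the residuals (1 under a
#' correct model) is reported as a summary statistic.
#'
#' @param cohort Cohort data frame with complete covariates.
#' @param params An [msm_params] object.
#' @param step Quadrature step for the marginal survival.
#' @return List with `residuals` (data frame `residual`, `event`),
#'   `summary` (grid of checked points), `slope`, `max_abs_dev`, `pass`.
#' @export
cox_snell_diagnostics <- function(cohort, params, step = 0.1) {
  died <- !is.na(cohort$death_time)
  t_end <- ifelse(died, cohort$death_time, cohort$followup_time)
  S <- marginal_os(cohort, params, t_end, step)
  if (any(!is.finite(S)) || any(S <= 0))
    abort("non-finite model survival in Cox-Snell residuals")
  r <- -log(S)
  fit <- survival::survfit(survival::Surv(r, died) ~ 1)
  grid <- stats::quantile(r, probs = seq(0.1, 0.9, by = 0.1))
  sm <- summary(fit, times = grid, extend = TRUE)
  km <- sm$surv
  se <- sm$std.err
  expct <- exp(-grid)
  inside <- abs(km - expct) <= 1.96 * pmax(se, 1e-8)
  # slope of the residuals' cumulative hazard vs the residuals (origin fit)
  ch <- -log(pmax(km, 1e-12))
  slope <- sum(ch * grid) / sum(grid^2)
  list(residuals = data.frame(residual = r, event = died),
       summary = data.frame(residual = as.numeric(grid), km = km,
                            expected = expct, se = se, inside = inside),
       slope = slope,
       max_abs_dev = max(abs(km - expct)),
       pass = mean(inside) >= 0.9)
}

#' Full validation report
#'
#' Applies the evaluation battery to a cohort and a parameter set:
#' time-dependent AUC and concordance for 5-year overall and event-free
#' survival (risk scores are the predicted 60-month death and any-event
#' probabilities), calibration by strata, and Cox-Snell diagnostics.
#' Persistent disease counts as an event at time zero for event-free
#' survival.
#'
#' @param cohort Cohort data frame with complete covariates.
#' @param params An [msm_params] object.
#' @param horizon AUC horizon in months (default 60).
#' @param strata Stratification columns for calibration.
#' @param step Quadrature step.
#' @return List of class `validation_report` with elements `auc_os_5yr`,
#'   `auc_efs_5yr`, `c_index_os`, `c_index_efs`, `calibration`,
#'   `cox_snell`.
#' @export
validation_report <- function(cohort, params, horizon = 60,
                              strata = c("ct", "p16"), step = 0.1) {
  occ <- cohort_occupancy(cohort, params, horizon, step)
  dead <- c("lrr_dead", "dm_dead", "persistent_dead", "dead_norec")
  risk_os <- rowSums(occ[, dead, 1])
  risk_efs <- 1 - occ[, "ef_alive", 1]
  died <- !is.na(cohort$death_time)
  t_os <- ifelse(died, cohort$death_time, cohort$followup_time)
  recur <- cohort$first_event %in% c("lrr", "dm")
  efs_event <- cohort$persistent | recur | died
  t_efs <- ifelse(cohort$persistent, 1e-6,
                  ifelse(recur, cohort$recurrence_time, t_os))
  structure(list(
    auc_os_5yr = as.numeric(time_dependent_auc(risk_os, t_os, died,
                                               horizon)),
    auc_efs_5yr = as.numeric(time_dependent_auc(risk_efs, t_efs, efs_event,
                                                horizon)),
    c_index_os = concordance_index(risk_os, t_os, died),
    c_index_efs = concordance_index(risk_efs, t_efs, efs_event),
    calibration = calibration_by_strata(cohort, params, strata,
                                        horizons = c(12, 36, horizon),
                                        step = step),
    cox_snell = cox_snell_diagnostics(cohort, params, step)),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  cat(sprintf("  AUC (5-yr OS)  %.3f   AUC (5-yr EFS) %.3f\n",
              x$auc_os_5yr, x$auc_efs_5yr))
  cat(sprintf("  C-index (OS)   %.3f   C-index (EFS)  %.3f\n",
              x$c_index_os, x$c_index_efs))
  cat(sprintf("  Cox-Snell: slope %.3f, max deviation %.3f, %s\n",
              x$cox_snell$slope, x$cox_snell$max_abs_dev,
              if (x$cox_snell$pass) "pass" else "FAIL"))
  cat(sprintf("  calibration rows: %d\n", nrow(x$calibration)))
  invisible(x)
}
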