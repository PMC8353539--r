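# Individualized state-occupancy prediction.
#
# At time t a patient occupies one of eight fine states: event-free alive,
# alive after LRR, alive after DM, alive with persistent disease, dead after
# LRR-first, dead after DM-first, dead with persistent disease, dead without
# recurrence. Reporting collapses these into four categories: (1) no event,
# (2) DM first (alive or dead), (3) LRR first or persistent disease, and
# (4) death without recurrence or persistence.
#
# For the noncured branch the post-recurrence terms are convolution
# integrals on the clock-reset scale,
#   integral_0^t h_k(u) exp(-(H3+H4+H5)(u)) S_k'(t - u) du,
# computed by composite Simpson quadrature on a 0.1-month grid with the
# 6-month change point as a mandatory knot.

FINE_STATES <- c("ef_alive", "lrr_alive", "dm_alive", "persistent_alive",
                 "lrr_dead", "dm_dead", "persistent_dead", "dead_norec")
REPORT_CATEGORIES <- c("no_event", "dm_first", "lrr_or_persistent",
                       "death_norec")

# Simpson nodes/weights on [from, t] with a knot at the change point. The
# leading subinterval [0, from] is excluded here and handled analytically by
# the callers through the cumulative hazard, because Weibull hazards with
# shape < 1 are singular at zero.
simpson_nodes <- function(t, cp = 6, step = 0.1, from = 0) {
  seg <- function(a, b) {
    m <- max(2L, 2L * ceiling((b - a) / (2 * step)))
    h <- (b - a) / m
    w <- c(1, rep(c(4, 2), length.out = m - 1), 1) * h / 3
    list(u = seq(a, b, length.out = m + 1), w = w)
  }
  if (t <= cp || from >= cp) {
    s <- seg(from, t)
  } else {
    s1 <- seg(from, cp); s2 <- seg(cp, t)
    s <- list(u = c(s1$u, s2$u), w = c(s1$w, s2$w))
  }
  s
}

# per-patient linear predictors for the hazard components
hazard_lps <- function(newdata, params) {
  specs <- params_specs(params)
  std <- params_std(params)
  out <- lapply(paste0("c", 3:8), function(id) {
    comp <- params[[id]]
    if (!length(comp$coef)) return(rep(0, nrow(newdata)))
    X <- encode_covariates(newdata, specs[[id]], std)
    if (anyNA(X))
      abort("missing covariates for %s; use predict_with_missing", id)
    drop(X %*% comp$coef)
  })
  names(out) <- paste0("c", 3:8)
  out
}

# fine-state occupancy for one patient at one time (u-vectorized Simpson);
# pr = (p_noncured, p_cured, p_persistent)
occ_fine_one <- function(params, pr, lp, t, step = 0.1) {
  pr <- unname(pr)
  S6 <- exp(-baseline_cumhaz(params$c6, t))
  S5 <- exp(-baseline_cumhaz(params$c5, t) * exp(lp$c5))
  out <- c(ef_alive = 0, lrr_alive = 0, dm_alive = 0,
           persistent_alive = pr[3] * S6,
           lrr_dead = 0, dm_dead = 0,
           persistent_dead = pr[3] * (1 - S6),
           dead_norec = pr[2] * (1 - S5))
  Sefs_fun <- function(u)
    exp(-(baseline_cumhaz(params$c3, u) * exp(lp$c3) +
          baseline_cumhaz(params$c4, u) * exp(lp$c4) +
          baseline_cumhaz(params$c5, u) * exp(lp$c5)))
  if (t <= 0) {
    out["ef_alive"] <- pr[1] + pr[2]
    return(out)
  }
  Sefs_t <- Sefs_fun(t)
  out["ef_alive"] <- pr[2] * S5 + pr[1] * Sefs_t

  # leading subinterval [0, a]: cumulative-hazard mass times the smooth
  # factors at the midpoint (robust to hazards singular at zero)
  a <- min(step, t)
  head_int <- function(id, lpk) {
    mass <- baseline_cumhaz(params[[id]], a) * exp(lpk) * Sefs_fun(a / 2)
    mass
  }
  Sp <- function(id, lpk, u)           # post-recurrence survival at t - u
    exp(-baseline_cumhaz(params[[id]], t - u) * exp(lpk))
  h3m <- head_int("c3", lp$c3); S7m <- Sp("c7", lp$c7, a / 2)
  h4m <- head_int("c4", lp$c4); S8m <- Sp("c8", lp$c8, a / 2)
  I <- c(lrr_a = h3m * S7m, lrr_d = h3m * (1 - S7m),
         dm_a = h4m * S8m, dm_d = h4m * (1 - S8m),
         norec = head_int("c5", lp$c5))
  if (t > a) {
    g <- simpson_nodes(t, cp = params$c3$change_point %||% 6, step = step,
                       from = a)
    Sefs <- Sefs_fun(g$u)
    k3 <- baseline_haz(params$c3, g$u) * exp(lp$c3) * Sefs
    k4 <- baseline_haz(params$c4, g$u) * exp(lp$c4) * Sefs
    h5 <- baseline_haz(params$c5, g$u) * exp(lp$c5) * Sefs
    S7 <- Sp("c7", lp$c7, g$u)
    S8 <- Sp("c8", lp$c8, g$u)
    I <- I + c(sum(g$w * k3 * S7), sum(g$w * k3 * (1 - S7)),
               sum(g$w * k4 * S8), sum(g$w * k4 * (1 - S8)),
               sum(g$w * h5))
  }
  # conservation: the five cause-specific paths partition 1 - Sefs(t)
  # exactly; quadrature fixes their split, the total is analytic
  tot <- sum(I)
  if (tot > 0) I <- I * (1 - Sefs_t) / tot
  out["lrr_alive"]  <- pr[1] * I[["lrr_a"]]
  out["lrr_dead"]   <- pr[1] * I[["lrr_d"]]
  out["dm_alive"]   <- pr[1] * I[["dm_a"]]
  out["dm_dead"]    <- pr[1] * I[["dm_d"]]
  out["dead_norec"] <- out["dead_norec"] + pr[1] * I[["norec"]]
  out
}

fine_to_report <- function(fine) {
  if (is.matrix(fine)) {
    cbind(no_event = fine[, "ef_alive"],
          dm_first = fine[, "dm_alive"] + fine[, "dm_dead"],
          lrr_or_persistent = fine[, "lrr_alive"] + fine[, "lrr_dead"] +
            fine[, "persistent_alive"] + fine[, "persistent_dead"],
          death_norec = fine[, "dead_norec"])
  } else fine_to_report(matrix(fine, 1, dimnames = list(NULL, names(fine))))
}

#' State-occupancy curve for one patient
#'
#' Computes the probability of occupying each fine state and each of the
#' four reporting categories over a time grid, marginalizing over the
#' latent initial state: the persistent branch uses C6 survival, the cured
#' branch C5 survival, and the noncured branch the competing-risk survivor
#' function together with clock-reset convolution integrals for the
#' post-recurrence states. Probabilities sum to one at every horizon.
#'
#' @param newdata One-row data frame of complete covariates.
#' @param params An [msm_params] object.
#' @param times Nondecreasing, nonnegative time grid in months.
#' @param step Quadrature step in months (default 0.1).
#' @return An object of class `occupancy_curve`: list with `times`, `fine`
#'   (matrix times x 8 fine states) and `report` (times x 4 categories).
#' @export
occupancy_curve <- function(newdata, params, times = 0:120, step = 0.1) {
  if (is.unsorted(times) || any(times < 0))
    abort("times must be a nondecreasing, nonnegative grid")
  newdata <- as.data.frame(newdata)
  if (nrow(newdata) != 1)
    abort("occupancy_curve expects a single patient; got %d rows",
          nrow(newdata))
  pr <- drop(initial_state_probs(newdata, params))
  pr <- c(pr["p_noncured"], pr["p_cured"], pr["p_persistent"])
  lp <- lapply(hazard_lps(newdata, params), function(v) v[1])
  fine <- t(vapply(times, function(t)
    occ_fine_one(params, pr, lp, t, step), numeric(8)))
  colnames(fine) <- FINE_STATES
  structure(list(times = times, fine = fine, report = fine_to_report(fine)),
            class = "occupancy_curve")
}

#' @export
print.occupancy_curve <- function(x, ...) {
  cat(sprintf("<occupancy_curve> %d time points, %g-%g months\n",
              length(x$times), min(x$times), max(x$times)))
  show <- x$times %in% c(0, 12, 36, 60, max(x$times))
  print(round(cbind(time = x$times[show], x$report[show, , drop = FALSE]),
              3), row.names = FALSE)
  invisible(x)
}

# fine-state occupancy for a cohort at a set of horizons; loops over
# quadrature nodes with n-vector arithmetic, so it scales to large cohorts
cohort_occupancy <- function(newdata, params, horizons, step = 0.1) {
  newdata <- as.data.frame(newdata)
  n <- nrow(newdata)
  pr <- initial_state_probs(newdata, params)
  lp <- hazard_lps(newdata, params)
  e3 <- exp(lp$c3); e4 <- exp(lp$c4); e5 <- exp(lp$c5)
  out <- array(0, c(n, 8, length(horizons)),
               dimnames = list(NULL, FINE_STATES, NULL))
  Sefs <- function(u)
    exp(-(baseline_cumhaz(params$c3, u) * e3 +
          baseline_cumhaz(params$c4, u) * e4 +
          baseline_cumhaz(params$c5, u) * e5))
  for (k in seq_along(horizons)) {
    t <- horizons[k]
    S6 <- exp(-baseline_cumhaz(params$c6, t))
    S5 <- exp(-baseline_cumhaz(params$c5, t) * e5)
    acc <- matrix(0, n, 5)  # lrr_alive, lrr_dead, dm_alive, dm_dead, norec
    Sefs_t <- if (t > 0) Sefs(t) else rep(1, n)
    if (t > 0) {
      a <- min(step, t)
      Sa <- Sefs(a / 2)
      S7a <- exp(-baseline_cumhaz(params$c7, t - a / 2) * exp(lp$c7))
      S8a <- exp(-baseline_cumhaz(params$c8, t - a / 2) * exp(lp$c8))
      m3 <- baseline_cumhaz(params$c3, a) * e3 * Sa
      m4 <- baseline_cumhaz(params$c4, a) * e4 * Sa
      acc[, 1] <- m3 * S7a
      acc[, 2] <- m3 * (1 - S7a)
      acc[, 3] <- m4 * S8a
      acc[, 4] <- m4 * (1 - S8a)
      acc[, 5] <- baseline_cumhaz(params$c5, a) * e5 * Sa
      if (t > a) {
        g <- simpson_nodes(t, cp = params$c3$change_point %||% 6,
                           step = step, from = a)
        for (j in seq_along(g$u)) {
          u <- g$u[j]
          Su <- Sefs(u)
          k3 <- baseline_haz(params$c3, u) * e3 * Su
          k4 <- baseline_haz(params$c4, u) * e4 * Su
          S7 <- exp(-baseline_cumhaz(params$c7, t - u) * exp(lp$c7))
          S8 <- exp(-baseline_cumhaz(params$c8, t - u) * exp(lp$c8))
          w <- g$w[j]
          acc[, 1] <- acc[, 1] + w * k3 * S7
          acc[, 2] <- acc[, 2] + w * k3 * (1 - S7)
          acc[, 3] <- acc[, 3] + w * k4 * S8
          acc[, 4] <- acc[, 4] + w * k4 * (1 - S8)
          acc[, 5] <- acc[, 5] + w * baseline_haz(params$c5, u) * e5 * Su
        }
      }
      tot <- rowSums(acc)
      f <- ifelse(tot > 0, (1 - Sefs_t) / tot, 1)
      acc <- acc * f
    }
    out[, "ef_alive", k] <- pr[, "p_cured"] * S5 +
      pr[, "p_noncured"] * Sefs_t
    out[, "lrr_alive", k] <- pr[, "p_noncured"] * acc[, 1]
    out[, "lrr_dead", k]  <- pr[, "p_noncured"] * acc[, 2]
    out[, "dm_alive", k]  <- pr[, "p_noncured"] * acc[, 3]
    out[, "dm_dead", k]   <- pr[, "p_noncured"] * acc[, 4]
    out[, "persistent_alive", k] <- pr[, "p_persistent"] * S6
    out[, "persistent_dead", k]  <- pr[, "p_persistent"] * (1 - S6)
    out[, "dead_norec", k] <- pr[, "p_cured"] * (1 - S5) +
      pr[, "p_noncured"] * acc[, 5]
  }
  out
}

#' Overall and event-free survival curves
#'
#' `OS(t)` is one minus the total dead occupancy; `EFS(t)` is the
#' event-free-alive occupancy (persistent disease counts as an event from
#' time zero, so the persistent branch never contributes to EFS).
#'
#' @inheritParams occupancy_curve
#' @return Data frame with columns `time`, `os`, `efs`.
#' @export
survival_curves <- function(newdata, params, times = 0:120, step = 0.1) {
  oc <- occupancy_curve(newdata, params, times, step)
  dead <- c("lrr_dead", "dm_dead", "persistent_dead", "dead_norec")
  data.frame(time = oc$times,
             os = 1 - rowSums(oc$fine[, dead, drop = FALSE]),
             efs = oc$fine[, "ef_alive"])
}

# per-patient marginal overall survival at the patient's own time
# (used by Cox-Snell residuals); same mixture as occupancy_curve
marginal_os <- function(newdata, params, t, step = 0.1) {
  newdata <- as.data.frame(newdata)
  n <- nrow(newdata)
  t <- rep_len(t, n)
  pr <- initial_state_probs(newdata, params)
  lp <- hazard_lps(newdata, params)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lpi <- lapply(lp, function(v) v[i])
    fine <- occ_fine_one(params, c(pr[i, "p_noncured"], pr[i, "p_cured"],
                                   pr[i, "p_persistent"]), lpi, t[i], step)
    out[i] <- fine["ef_alive"] + fine["lrr_alive"] + fine["dm_alive"] +
      fine["persistent_alive"]
  }
  out
}

#' Predict with missing covariates via imputation averaging
#'
#' Draws `M` completions of the patient's missing covariates from the
#' chained-equations conditional models of an [imputer] fit to a reference
#' cohort, computes the occupancy curve for each completion at the supplied
#' (typically posterior-mean) parameters, and averages. Averaging convex
#' combinations preserves the sum-to-one property. With no missing fields
#' the result equals [occupancy_curve()] for any `M`.
#'
#' @param newdata One-row data frame; `NA` marks missing covariates.
#' @param params An [msm_params] object (posterior means for prediction).
#' @param imputer An [imputer] object from [build_imputer()]; required only
#'   when covariates are missing.
#' @param times Time grid (months).
#' @param M Number of imputations to average over (default 10).
#' @param step Quadrature step.
#' @return An `occupancy_curve`.
#' @export
predict_with_missing <- function(newdata, params, imputer = NULL,
                                 times = 0:120, M = 10, step = 0.1) {
  newdata <- as.data.frame(newdata)
  used <- unique(unlist(lapply(params_specs(params), `[[`, "covariates")))
  have <- intersect(used, names(newdata))
  miss <- setdiff(used, have)
  missing_any <- length(miss) > 0 ||
    anyNA(newdata[, have, drop = FALSE])
  if (!missing_any) return(occupancy_curve(newdata, params, times, step))
  if (is.null(imputer))
    abort("covariates are missing (%s); supply an imputer",
          toString(union(miss, have[colSums(is.na(
        newdata[, have, drop = FALSE])) > 0])))
  acc_fine <- NULL
  for (m in seq_len(M)) {
    filled <- impute_draw(imputer, newdata)
    oc <- occupancy_curve(filled, params, times, step)
    acc_fine <- if (is.null(acc_fine)) oc$fine else acc_fine + oc$fine
  }
  fine <- acc_fine / M
  structure(list(times = times, fine = fine,
                 report = fine_to_report(fine)),
            class = "occupancy_curve")
}

#' Individualized patient report
#'
#' Tabulates the four-category outcome probabilities on a monthly grid
#' through the reporting horizon, plus scalar 5-year overall and event-free
#' survival, for a single patient.
#'
#' @param newdata One-row data frame of complete covariates.
#' @param params An [msm_params] object.
#' @param horizon Reporting horizon in months (default 60).
#' @param step Quadrature step.
#' @return Data frame with `time` and the four category columns; 60-month
#'   (or horizon) OS/EFS are attached as attributes `os_5yr` and `efs_5yr`.
#' @export
patient_report <- function(newdata, params, horizon = 60, step = 0.1) {
  times <- 0:horizon
  oc <- occupancy_curve(newdata, params, times, step)
  dead <- c("lrr_dead", "dm_dead", "persistent_dead", "dead_norec")
  rep_df <- data.frame(time = times, oc$report)
  attr(rep_df, "os_5yr") <- unname(
    1 - rowSums(oc$fine[, dead, drop = FALSE])[length(times)])
  attr(rep_df, "efs_5yr") <- unname(oc$fine[length(times), "ef_alive"])
  rep_df
}
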