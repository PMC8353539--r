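# Bayesian estimation by Metropolis-within-Gibbs: adaptive random-walk
# Metropolis updates of each parameter, data augmentation of the latent
# cured/noncured state, and chained-equations imputation of missing
# covariates inside the chain. Given the augmented states the complete-data
# likelihood factorizes over the eight components, so each parameter update
# touches only its own component's factor.

#' Prior specification
#'
#' Independent normal priors: `N(0, coef_sd^2)` on coefficients and
#' intercepts, `N(log_shape_mean, log_shape_sd^2)` on log Weibull shapes and
#' `N(log_scale_mean, log_scale_sd^2)` on log scales (months). Order
#' restrictions truncate the prior to zero on parameter sets violating a
#' nondecreasing chain -- by default the distant-metastasis (C4) log hazard
#' ratios must be nondecreasing across cN categories, starting from the
#' reference at zero.
#'
#' @param coef_sd,intercept_sd,log_shape_mean,log_shape_sd,log_scale_mean,
#'   log_scale_sd Hyperparameters of the normal priors.
#' @param order_restrictions List of restrictions, each a list with
#'   `component`, `columns` (coefficient names in increasing order) and
#'   `include_reference` (prepend 0 to the chain?).
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(coef_sd = 2.5, intercept_sd = 2.5,
                       log_shape_mean = 0, log_shape_sd = 1,
                       log_scale_mean = 3, log_scale_sd = 2,
                       order_restrictions = list(
                         list(component = "c4",
                              columns = c("cn_N2abc", "cn_N3"),
                              include_reference = TRUE))) {
  structure(list(coef_sd = coef_sd, intercept_sd = intercept_sd,
                 log_shape_mean = log_shape_mean,
                 log_shape_sd = log_shape_sd,
                 log_scale_mean = log_scale_mean,
                 log_scale_sd = log_scale_sd,
                 order_restrictions = order_restrictions),
            class = "prior_spec")
}

prior_mean_sd <- function(par_names, prior) {
  base <- sub("^c[0-9]+\\.", "", par_names)
  mean <- ifelse(grepl("^log_shape", base), prior$log_shape_mean,
          ifelse(grepl("^log_scale", base), prior$log_scale_mean, 0))
  sd <- ifelse(grepl("^log_shape", base), prior$log_shape_sd,
        ifelse(grepl("^log_scale", base), prior$log_scale_sd,
        ifelse(base == "intercept", prior$intercept_sd, prior$coef_sd)))
  list(mean = mean, sd = sd)
}

order_ok <- function(params, prior) {
  for (r in prior$order_restrictions) {
    v <- params[[r$component]]$coef[r$columns]
    if (anyNA(v))
      abort("order restriction names unknown coefficients: %s",
            toString(r$columns))
    chain <- c(if (isTRUE(r$include_reference)) 0, unname(v))
    if (any(diff(chain) < 0)) return(FALSE)
  }
  TRUE
}

#' Log prior density
#'
#' Sum of the per-parameter normal log densities (baseline parameters on the
#' log scale), or `-Inf` when an order restriction is violated.
#'
#' @param params An [msm_params] object.
#' @param prior A [prior_spec()].
#' @return Scalar log density.
#' @export
log_prior <- function(params, prior = prior_spec()) {
  if (!order_ok(params, prior)) return(-Inf)
  theta <- flatten_params(params)
  ms <- prior_mean_sd(names(theta), prior)
  sum(stats::dnorm(theta, ms$mean, ms$sd, log = TRUE))
}

#' Draw latent initial states
#'
#' For each nonpersistent, recurrence-free record the initial state is
#' latent; its full conditional is Bernoulli between noncured (1) and cured
#' (2) with probability proportional to the complete-data likelihood of each
#' branch, which reduces to `q * exp(-(H3 + H4)(t)) : (1 - q)` where `q` is
#' the C2 probability of noncure and `t` the censoring/death time. Records
#' with an observed state are returned unchanged.
#'
#' @param cohort Cohort data frame with complete covariates.
#' @param params An [msm_params] object.
#' @return Integer vector of sampled initial states (1, 2 or 6).
#' @export
sample_latent_states <- function(cohort, params) {
  dat <- prep_msm_data(cohort, params)
  draw_states(params, dat)
}

draw_states <- function(params, dat) {
  state <- ifelse(dat$persistent, 6L, ifelse(dat$known1, 1L, NA_integer_))
  amb <- which(dat$ambiguous)
  if (length(amb)) {
    p1 <- state1_posterior(params, dat, amb)
    state[amb] <- ifelse(stats::runif(length(amb)) < p1, 1L, 2L)
  }
  state
}

# --- chained-equations imputation ----------------------------------------

IMPUTE_ORDER <- c("age", "sex", "smoking", "ct", "cn", "ace27", "anemia",
                  "p16", "log_mtv", "rece")
BINARY_VARS <- c("anemia", "rece")
CONT_VARS <- c("age", "log_mtv")

# numeric predictor encoding of covariates (+ optional outcome summaries)
impute_predictors <- function(completed, outcome = TRUE) {
  lv <- COVARIATE_LEVELS
  X <- data.frame(
    age = as.numeric(completed$age),
    sex_f = as.numeric(completed$sex == "female"),
    ace27 = as.numeric(factor(completed$ace27, lv$ace27)) - 1,
    smoking = as.numeric(factor(completed$smoking, lv$smoking)) - 1,
    anemia = as.numeric(completed$anemia),
    p16_neg = as.numeric(completed$p16 == "negative"),
    ct = as.numeric(factor(completed$ct, lv$ct)) - 1,
    cn = as.numeric(factor(completed$cn, lv$cn)) - 1)
  if (!is.null(completed$log_mtv)) X$log_mtv <- completed$log_mtv
  if (!is.null(completed$rece)) X$rece <- as.numeric(completed$rece)
  if (outcome && !is.null(completed$first_event)) {
    died <- !is.na(completed$death_time)
    t_end <- ifelse(died, completed$death_time, completed$followup_time)
    X$ev_any <- as.numeric(completed$persistent |
                             completed$first_event != "none")
    X$log_fu <- log(pmax(t_end, 0.1))
  }
  X
}

pred_cols_for <- function(var, X) {
  drop_map <- c(age = "age", sex = "sex_f", ace27 = "ace27",
                smoking = "smoking", anemia = "anemia", p16 = "p16_neg",
                ct = "ct", cn = "cn", log_mtv = "log_mtv", rece = "rece")
  setdiff(names(X), drop_map[[var]])
}

fit_conditional <- function(var, completed, obs_rows, outcome = TRUE) {
  X <- impute_predictors(completed, outcome)
  cols <- pred_cols_for(var, X)
  df <- X[obs_rows, cols, drop = FALSE]
  y <- completed[[var]][obs_rows]
  fit <- tryCatch(suppressWarnings({
    if (var %in% CONT_VARS) {
      m <- stats::lm(y ~ ., data = cbind(y = as.numeric(y), df))
      list(type = "lm", fit = m, sigma = summary(m)$sigma, cols = cols)
    } else if (var %in% BINARY_VARS) {
      m <- stats::glm(y ~ ., data = cbind(y = as.numeric(y), df),
                      family = stats::binomial())
      list(type = "glm", fit = m, cols = cols)
    } else if (var %in% c("sex", "p16")) {
      lv <- COVARIATE_LEVELS[[var]]
      m <- stats::glm(y ~ ., family = stats::binomial(),
                      data = cbind(y = as.numeric(y == lv[2]), df))
      list(type = "glm2", fit = m, cols = cols, levels = lv)
    } else {
      lv <- COVARIATE_LEVELS[[var]]
      m <- nnet::multinom(y ~ ., data = cbind(y = factor(y, lv), df),
                          trace = FALSE, maxit = 200)
      list(type = "multinom", fit = m, cols = cols, levels = lv)
    }
  }), error = function(e) NULL)
  if (is.null(fit)) {           # degenerate fit: fall back to the marginal
    fit <- list(type = "marginal", values = y,
                cols = character())
  }
  fit
}

draw_conditional <- function(model, completed, rows, outcome = TRUE) {
  n <- length(rows)
  if (model$type == "marginal")
    return(sample(model$values, n, replace = TRUE))
  X <- impute_predictors(completed, outcome)
  df <- X[rows, model$cols, drop = FALSE]
  if (model$type == "lm") {
    mu <- stats::predict(model$fit, newdata = df)
    stats::rnorm(n, mu, model$sigma)
  } else if (model$type == "glm") {
    p <- stats::predict(model$fit, newdata = df, type = "response")
    stats::runif(n) < p
  } else if (model$type == "glm2") {
    p <- stats::predict(model$fit, newdata = df, type = "response")
    ifelse(stats::runif(n) < p, model$levels[2], model$levels[1])
  } else {
    p <- stats::predict(model$fit, newdata = df, type = "probs")
    if (!is.matrix(p)) p <- matrix(p, nrow = n, byrow = n == 1)
    apply(p, 1, function(pr) sample(model$levels, 1, prob = pr))
  }
}

# initial fill: draw each missing cell from the observed marginal
impute_init <- function(cohort) {
  out <- cohort
  for (v in intersect(IMPUTE_ORDER, names(cohort))) {
    na <- is.na(out[[v]])
    if (any(na)) {
      obs <- out[[v]][!na]
      if (!length(obs)) abort("covariate '%s' is entirely missing", v)
      out[[v]][na] <- sample(obs, sum(na), replace = TRUE)
    }
  }
  out
}

#' One chained-equations imputation cycle
#'
#' Cycles through the covariates that have missing values in `cohort` (in a
#' fixed order), refits each conditional model on the rows where the
#' covariate was observed -- logistic for binary, multinomial for
#' categorical, linear for continuous covariates, with the other current
#' covariate values plus an any-event indicator and log follow-up time as
#' predictors -- and redraws the originally missing cells from the fitted
#' conditional. Observed cells never change.
#'
#' @param cohort The cohort with its original `NA` pattern.
#' @param completed A fully completed version of `cohort` (e.g. the previous
#'   cycle's output, or the initial marginal fill).
#' @param outcome Include outcome summaries among the predictors?
#' @return An updated completed cohort.
#' @export
impute_step <- function(cohort, completed = impute_init(cohort),
                        outcome = TRUE) {
  if (anyNA(completed[, intersect(IMPUTE_ORDER, names(completed))]))
    abort("'completed' still has missing covariate cells")
  for (v in intersect(IMPUTE_ORDER, names(cohort))) {
    na <- which(is.na(cohort[[v]]))
    if (!length(na)) next
    model <- fit_conditional(v, completed, which(!is.na(cohort[[v]])),
                             outcome)
    completed[[v]][na] <- draw_conditional(model, completed, na, outcome)
  }
  completed
}

#' Build a prediction-time imputer
#'
#' Fits the chained-equations conditional models for every covariate on a
#' completed reference cohort (no outcome predictors, since predictions are
#' made before outcomes exist). The result is used by
#' [predict_with_missing()] to draw completions of a new patient's missing
#' covariates.
#'
#' @param completed A completed covariate table (no `NA`s in the covariate
#'   columns), e.g. an element of the `imputations` kept by [run_mcmc()].
#' @return An object of class `imputer`.
#' @export
build_imputer <- function(completed) {
  vars <- intersect(IMPUTE_ORDER, names(completed))
  models <- lapply(vars, function(v)
    fit_conditional(v, completed, seq_len(nrow(completed)),
                    outcome = FALSE))
  names(models) <- vars
  marginals <- lapply(vars, function(v) completed[[v]])
  names(marginals) <- vars
  structure(list(models = models, marginals = marginals, vars = vars),
            class = "imputer")
}

# draw one completion of a (possibly one-row) covariate table; two
# chained passes after a marginal initialization
impute_draw <- function(imputer, newdata, cycles = 2) {
  out <- as.data.frame(newdata)
  miss <- lapply(imputer$vars, function(v)
    if (is.null(out[[v]])) seq_len(nrow(out)) else which(is.na(out[[v]])))
  names(miss) <- imputer$vars
  for (v in imputer$vars)
    if (length(miss[[v]]))
      out[[v]][miss[[v]]] <- sample(imputer$marginals[[v]],
                                    length(miss[[v]]), replace = TRUE)
  for (cy in seq_len(cycles))
    for (v in imputer$vars)
      if (length(miss[[v]]))
        out[[v]][miss[[v]]] <- draw_conditional(imputer$models[[v]], out,
                                                miss[[v]], outcome = FALSE)
  out
}

# --- the sampler ---------------------------------------------------------

# maximum-likelihood-style initial values: logistic fits for C1/C2 with
# latent states at their most probable values (short recurrence-free
# follow-up counted as noncured), intercept-only Weibull fits for the
# baselines, hazard coefficients at zero; falls back to moment-style
# estimates when a fit degenerates
init_params <- function(specs, dat, standardization) {
  p <- null_params(specs, standardization)
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  exp_scale <- function(time, event, rows)
    clamp(sum(time[rows]) / max(sum(event[rows]), 1), 2, 400)

  fit_logistic <- function(id, y, rows) {
    X <- dat$X[[id]][rows, , drop = FALSE]
    co <- tryCatch(suppressWarnings(
      stats::coef(stats::glm(y[rows] ~ X, family = stats::binomial()))),
      error = function(e) NULL)
    if (is.null(co) || anyNA(co) || any(abs(co) > 8)) {
      p[[id]]$intercept <<- stats::qlogis(clamp(mean(y[rows]), 0.02, 0.9))
    } else {
      p[[id]]$intercept <<- co[1]
      if (length(p[[id]]$coef))
        p[[id]]$coef[] <<- unname(co[-1])
    }
  }
  fit_logistic("c1", dat$persistent, seq_len(dat$n))
  y2 <- dat$known1 | (dat$ambiguous & dat$t1 < 24)  # most probable states
  fit_logistic("c2", y2, which(!dat$persistent))

  fit_weib <- function(time, event, rows, fallback_scale) {
    out <- tryCatch({
      f <- survival::survreg(
        survival::Surv(pmax(time[rows], 1e-3), event[rows]) ~ 1,
        dist = "weibull")
      c(shape = 1 / f$scale, scale = exp(unname(stats::coef(f)[1])))
    }, error = function(e) NULL)
    if (is.null(out) || any(!is.finite(out)) || any(out <= 0))
      out <- c(shape = 1, scale = fallback_scale)
    c(clamp(out[1], 0.2, 5), clamp(out[2], 2, 2000))
  }
  np <- which(!dat$persistent)
  w3 <- fit_weib(dat$t1, dat$ev == "lrr", np, exp_scale(dat$t1,
                 dat$ev == "lrr", np))
  w4 <- fit_weib(dat$t1, dat$ev == "dm", np, exp_scale(dat$t1,
                 dat$ev == "dm", np))
  w5 <- fit_weib(dat$t1, dat$ev == "death" & !dat$recur, np,
                 exp_scale(dat$t1, dat$ev == "death" & !dat$recur, np))
  p$c3[c("shape1", "scale1", "shape2", "scale2")] <-
    list(w3[1], w3[2], w3[1], w3[2])
  p$c4[c("shape1", "scale1", "shape2", "scale2")] <-
    list(w4[1], w4[2], w4[1], w4[2])
  p$c5[c("shape", "scale")] <- list(w5[1], w5[2])
  ip <- which(dat$persistent)
  w6 <- fit_weib(dat$t_end, dat$died, ip,
                 exp_scale(dat$t_end, dat$died, ip))
  p$c6[c("shape", "scale")] <- list(w6[1], w6[2])
  for (id in c("c7", "c8")) {
    rows <- which(dat$ev == if (id == "c7") "lrr" else "dm")
    w <- fit_weib(dat$t2, dat$died, rows,
                  exp_scale(dat$t2, dat$died, rows))
    p[[id]][c("shape", "scale")] <- list(w[1], w[2])
  }
  p
}

# which component's likelihood factor a flat parameter belongs to
par_component <- function(par_names) sub("\\..*$", "", par_names)

#' Fit the multistate cure model by MCMC
#'
#' Metropolis-within-Gibbs sampler alternating (a) a chained-equations
#' imputation cycle for missing covariates (every `impute_every` iterations),
#' (b) a draw of the latent cured/noncured state for every ambiguous record,
#' and (c) an adaptive random-walk Metropolis update of every parameter
#' against its component's complete-data likelihood factor plus the prior.
#' Step sizes adapt toward a 44% acceptance rate during burn-in only, so the
#' retained chain is a valid Markov chain. Order-restricted priors are
#' enforced by rejecting violating proposals. The run is reproducible: the
#' same seed, data and configuration give identical draws.
#'
#' @param cohort Cohort data frame (see [read_cohort()] for the schema).
#' @param prior A [prior_spec()].
#' @param specs Component specifications from [component_specs()].
#' @param n_iter,burnin Total iterations and burn-in (defaults 25000 and
#'   10000).
#' @param seed Integer seed for all randomness in the run.
#' @param impute_every Refit/redraw missing covariates every this many
#'   iterations (ignored when the cohort is complete).
#' @param n_imputations Completed data sets to retain for prediction-time
#'   averaging (default 10).
#' @param standardization Standardization constants for continuous
#'   covariates.
#' @param progress Print a progress line every 1000 iterations?
#' @return An object of class `msm_draws`: post-burn-in draws (matrix), the
#'   parameter template, acceptance rates, retained imputations, latent
#'   state frequencies and the seed.
#' @export
run_mcmc <- function(cohort, prior = prior_spec(),
                     specs = component_specs(),
                     n_iter = 25000, burnin = 10000, seed = 1,
                     impute_every = 10, n_imputations = 10,
                     standardization = default_standardization(),
                     progress = FALSE, .fixed_states = NULL) {
  if (burnin >= n_iter) abort("burnin must be smaller than n_iter")
  set.seed(seed)
  covs <- intersect(IMPUTE_ORDER, names(cohort))
  used <- unique(unlist(lapply(specs, `[[`, "covariates")))
  has_missing <- anyNA(cohort[, intersect(covs, used)])
  completed <- if (has_missing) impute_init(cohort) else cohort

  template <- null_params(specs, standardization)
  dat <- prep_msm_data(completed, template)
  cur <- init_params(specs, dat, standardization)
  theta <- flatten_params(cur)
  npar <- length(theta)
  ms <- prior_mean_sd(names(theta), prior)
  comp_of <- par_component(names(theta))
  state <- .fixed_states %||% draw_states(cur, dat)
  if (!is.finite(complete_loglik_cohort(cur, dat, state))) {
    bad <- which(!is.finite(vapply(seq_len(dat$n), function(i) {
      r <- completed[i, ]
      complete_data_loglik(r, state[i], cur)
    }, numeric(1))))
    abort("non-finite likelihood at initialization (record %s)",
          toString(utils::head(completed$id[bad], 5)))
  }

  # default mode: collapsed updates for C2/C3/C4 (latent state summed out);
  # with .fixed_states the complete-data factors are used throughout
  use_marg <- is.null(.fixed_states)
  cache <- if (use_marg) marg_cache(cur, dat)
  piece_slot <- c(c2 = "q", c3 = "H3", c4 = "H4")
  comp_ll <- function(id, pp) {
    if (use_marg && id %in% names(piece_slot))
      marg_loglik(id, pp, dat, cache)
    else list(val = component_loglik(id, pp, dat, state), piece = NULL)
  }
  kn <- c(c2 = 0, c3 = 0, c4 = 0)   # known-state terms of collapsed factors
  M <- 0                            # shared latent-state mixture term
  refresh_ll <- function() {
    ll <- vapply(paste0("c", 1:8), function(id) comp_ll(id, cur)$val,
                 numeric(1))
    if (use_marg) {
      for (id in names(kn)) {
        r <- comp_ll(id, cur)
        kn[id] <<- r$kn
        M <<- r$M
        ll[id] <- r$val
      }
    }
    ll
  }
  ll <- refresh_ll()
  lstep <- rep(log(0.1), npar)
  acc_count <- prop_count <- rep(0, npar)
  keep <- matrix(NA_real_, n_iter - burnin, npar,
                 dimnames = list(NULL, names(theta)))
  imputations <- list()
  imp_slots <- if (has_missing)
    unique(impute_every * round(seq(burnin + impute_every, n_iter,
                                    length.out = n_imputations) /
                                  impute_every)) else integer()

  for (it in seq_len(n_iter)) {
    if (has_missing && it %% impute_every == 0) {
      completed <- impute_step(cohort, completed)
      dat <- prep_msm_data(completed, template)
      if (use_marg) cache <- marg_cache(cur, dat)
      ll <- refresh_ll()
      if (it %in% imp_slots)
        imputations[[length(imputations) + 1]] <- completed
    }
    if (use_marg) state <- draw_states(cur, dat)

    ord <- sample.int(npar)             # random-scan over parameters
    z <- stats::rnorm(npar)
    u <- stats::runif(npar)
    for (j in ord) {
      id <- comp_of[j]
      old <- theta[j]
      prop <- old + z[j] * exp(lstep[j])
      theta[j] <- prop
      cand <- unflatten_component(cur, id, theta, comp_of)
      lp_ratio <- stats::dnorm(prop, ms$mean[j], ms$sd[j], log = TRUE) -
        stats::dnorm(old, ms$mean[j], ms$sd[j], log = TRUE)
      ok <- order_ok_component(cand, id, prior)
      if (ok) {
        res <- comp_ll(id, cand)
        accept <- is.finite(res$val) &&
          log(u[j]) < res$val - ll[id] + lp_ratio
      } else accept <- FALSE
      if (accept) {
        cur <- cand
        ll[id] <- res$val
        if (use_marg && id %in% names(piece_slot)) {
          cache[[piece_slot[[id]]]] <- res$piece
          kn[id] <- res$kn
          M <- res$M
          ll[names(kn)] <- kn + M  # shared term: refresh all three factors
        }
        acc_count[j] <- acc_count[j] + 1
      } else theta[j] <- old
      prop_count[j] <- prop_count[j] + 1
      if (it <= burnin)
        lstep[j] <- lstep[j] + it^-0.55 * ((if (accept) 1 else 0) - 0.44)
    }
    if (it > burnin) keep[it - burnin, ] <- theta
    if (progress && it %% 1000 == 0)
      message(sprintf("iter %d / %d, mean acceptance %.2f", it, n_iter,
                      mean(acc_count / pmax(prop_count, 1))))
  }
  structure(list(draws = keep, n_iter = n_iter, burnin = burnin,
                 template = template,
                 acceptance = acc_count / pmax(prop_count, 1),
                 imputations = imputations,
                 seed = seed, prior = prior,
                 state1_fraction = mean(state[!dat$persistent] == 1)),
            class = "msm_draws")
}

# replace one component of `cur` from the flat vector `theta`
unflatten_component <- function(cur, id, theta, comp_of) {
  sel <- theta[comp_of == id]
  names(sel) <- sub("^c[0-9]+\\.", "", names(sel))
  comp <- cur[[id]]
  if (!is.null(comp$intercept)) comp$intercept <- unname(sel["intercept"])
  else if (!is.null(comp$change_point)) {
    comp$shape1 <- exp(unname(sel["log_shape1"]))
    comp$scale1 <- exp(unname(sel["log_scale1"]))
    comp$shape2 <- exp(unname(sel["log_shape2"]))
    comp$scale2 <- exp(unname(sel["log_scale2"]))
  } else {
    comp$shape <- exp(unname(sel["log_shape"]))
    comp$scale <- exp(unname(sel["log_scale"]))
  }
  if (length(comp$coef))
    comp$coef <- named(sel[names(comp$coef)], names(comp$coef))
  cur[[id]] <- comp
  cur
}

order_ok_component <- function(params, id, prior) {
  for (r in prior$order_restrictions) {
    if (r$component != id) next
    chain <- c(if (isTRUE(r$include_reference)) 0,
               unname(params[[id]]$coef[r$columns]))
    if (any(diff(chain) < 0)) return(FALSE)
  }
  TRUE
}

#' @export
print.msm_draws <- function(x, ...) {
  cat(sprintf(
    "<msm_draws> %d kept draws (%d iterations, %d burn-in), %d parameters\n",
    nrow(x$draws), x$n_iter, x$burnin, ncol(x$draws)))
  cat(sprintf("  acceptance rates: %.2f-%.2f (median %.2f); seed %d\n",
              min(x$acceptance), max(x$acceptance),
              stats::median(x$acceptance), x$seed))
  invisible(x)
}

#' Posterior summaries
#'
#' Posterior means and equal-tailed 95% credible intervals per parameter,
#' with logistic coefficients also reported as odds ratios and hazard
#' coefficients as hazard ratios, mirroring the component/covariate panel
#' layout of the fitted-model report. A split-half R-hat per parameter is
#' included as a convergence diagnostic.
#'
#' @param draws An `msm_draws` object from [run_mcmc()].
#' @return Data frame with columns `component`, `term`, `type`, `mean`,
#'   `lower`, `upper` (sampling scale), `ratio`, `ratio_lower`,
#'   `ratio_upper` (exp scale, coefficients and intercepts only) and
#'   `rhat`.
#' @export
posterior_summary <- function(draws) {
  m <- draws$draws
  if (!nrow(m)) abort("no post-burn-in draws")
  comp <- par_component(colnames(m))
  term <- sub("^c[0-9]+\\.", "", colnames(m))
  type <- ifelse(term == "intercept", "intercept",
          ifelse(grepl("^log_", term), "baseline", "coef"))
  qs <- t(apply(m, 2, stats::quantile, probs = c(0.025, 0.975)))
  half <- nrow(m) %/% 2
  rhat <- vapply(seq_len(ncol(m)), function(j) {
    a <- m[seq_len(half), j]; b <- m[half + seq_len(half), j]
    W <- (stats::var(a) + stats::var(b)) / 2
    B <- half * (mean(a) - mean(b))^2 / 2
    if (W <= 0) return(1)
    sqrt(((half - 1) / half * W + B / half) / W)
  }, numeric(1))
  ratio <- ifelse(type == "baseline", NA, exp(colMeans(m)))
  data.frame(component = comp, term = term, type = type,
             mean = colMeans(m), lower = qs[, 1], upper = qs[, 2],
             ratio = ratio,
             ratio_lower = ifelse(type == "baseline", NA, exp(qs[, 1])),
             ratio_upper = ifelse(type == "baseline", NA, exp(qs[, 2])),
             rhat = rhat, row.names = NULL)
}

#' Posterior-mean parameters
#'
#' Collapses a set of draws to an [msm_params] object at the posterior mean
#' of every parameter (means taken on the sampling scale, i.e. log scale for
#' baseline parameters), the plug-in used for individualized prediction.
#'
#' @param draws An `msm_draws` object.
#' @return An [msm_params] object.
#' @export
posterior_mean_params <- function(draws) {
  unflatten_params(colMeans(draws$draws), draws$template)
}
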