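# shared fixtures: reference patients, toy records, small parameter sets

ref_patient <- function(...) {
  out <- data.frame(age = 58, sex = "male", ace27 = "none",
                    smoking = "never", anemia = FALSE, p16 = "positive",
                    ct = "T1", cn = "N0", log_mtv = log(13.6), rece = FALSE,
                    stringsAsFactors = FALSE)
  mods <- list(...)
  for (nm in names(mods)) out[[nm]] <- mods[[nm]]
  out
}

# a patient record row: covariates + outcome fields
toy_record <- function(persistent = FALSE, first_event = "none",
                       recurrence_time = NA_real_, death_time = NA_real_,
                       followup_time = 60, covariates = ref_patient()) {
  cbind(id = "T1", covariates,
        data.frame(persistent = persistent, first_event = first_event,
                   recurrence_time = recurrence_time,
                   death_time = death_time, followup_time = followup_time,
                   cured_label = FALSE))
}

# reference parameter set with mildly perturbed values for property tests
random_params <- function(seed) {
  set.seed(seed)
  p <- reference_params()
  for (id in paste0("c", 1:8)) {
    if (length(p[[id]]$coef))
      p[[id]]$coef <- p[[id]]$coef + stats::rnorm(length(p[[id]]$coef),
                                                  0, 0.3)
    if (!is.null(p[[id]]$intercept))
      p[[id]]$intercept <- p[[id]]$intercept + stats::rnorm(1, 0, 0.3)
    for (nm in intersect(names(p[[id]]),
                         c("shape", "shape1", "shape2")))
      p[[id]][[nm]] <- p[[id]][[nm]] * exp(stats::rnorm(1, 0, 0.25))
    for (nm in intersect(names(p[[id]]),
                         c("scale", "scale1", "scale2")))
      p[[id]][[nm]] <- p[[id]][[nm]] * exp(stats::rnorm(1, 0, 0.25))
  }
  # keep the metastasis cN ordering restriction satisfied
  p$c4$coef["cn_N2abc"] <- abs(p$c4$coef["cn_N2abc"])
  p$c4$coef["cn_N3"] <- p$c4$coef["cn_N2abc"] + abs(p$c4$coef["cn_N3"])
  p
}

random_covariates <- function(seed, n = 1) {
  set.seed(seed)
  data.frame(
    age = round(stats::rnorm(n, 58, 9), 1),
    sex = sample(c("male", "female"), n, TRUE),
    ace27 = sample(c("none", "mild", "moderate", "severe"), n, TRUE),
    smoking = sample(c("never", "former", "current"), n, TRUE),
    anemia = sample(c(TRUE, FALSE), n, TRUE),
    p16 = sample(c("positive", "negative"), n, TRUE),
    ct = sample(c("T1", "T2", "T3", "T4"), n, TRUE),
    cn = sample(c("N0", "N1", "N2abc", "N3"), n, TRUE),
    log_mtv = stats::rnorm(n, log(13.6), 0.67),
    rece = sample(c(TRUE, FALSE), n, TRUE),
    stringsAsFactors = FALSE)
}

no_missingness <- list(anemia = 0, ace27 = 0, smoking = 0, ct = 0, cn = 0,
                       p16 = 0, imaging = 0)

# Monte Carlo estimate of the four report categories at time t0 from
# simulated trajectories (independent oracle for occupancy_curve)
mc_report <- function(truths, t0) {
  alive <- truths$death_time > t0
  norec <- is.na(truths$recurrence_time) | truths$recurrence_time > t0
  c(no_event = mean(truths$true_state != 6 & norec & alive),
    dm_first = mean(truths$recurrence_type == "dm" & !norec),
    lrr_or_persistent = mean((truths$recurrence_type == "lrr" & !norec) |
                               truths$true_state == 6),
    death_norec = mean(truths$true_state != 6 & norec & !alive))
}
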