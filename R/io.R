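# Cohort readers/writers with schema validation, and a pipeline driver
# wiring simulate -> fit -> predict -> validate.

COHORT_COLUMNS <- c("id", "age", "sex", "ace27", "smoking", "anemia", "p16",
                    "ct", "cn", "log_mtv", "rece", "persistent",
                    "first_event", "recurrence_time", "death_time",
                    "followup_time", "cured_label")

# atomic write: temp file in the same directory, then rename
write_atomic <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Write a cohort CSV
#'
#' Writes the documented cohort schema with `NA` for missing cells and a
#' comment header recording the package version and, when available, the
#' generating seed.
#'
#' @param cohort Cohort data frame.
#' @param path Output path.
#' @param seed Optional seed to record in the metadata header.
#' @export
write_cohort <- function(cohort, path, seed = NULL) {
  write_atomic(function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    writeLines(sprintf("# curemsm cohort v%s%s",
                       as.character(utils::packageVersion("curemsm")),
                       if (!is.null(seed)) sprintf(" seed=%d", seed) else ""),
               con)
    utils::write.csv(cohort, con, row.names = FALSE)
  }, path)
}

#' Read and validate a cohort CSV
#'
#' Reads the documented cohort schema, types every column, and validates
#' record-level invariants: category levels, nonnegative times, recurrence
#' before death, and the persistence rule that a persistent record carries
#' no recurrence transition. Row-level problems are aggregated and reported
#' with row numbers. `NA` cells are missing values, never category levels.
#'
#' @param path Path to a cohort CSV (as written by [write_cohort()]).
#' @param strict Reject unknown columns?
#' @return Validated cohort data frame.
#' @export
read_cohort <- function(path, strict = FALSE) {
  df <- utils::read.csv(path, comment.char = "#",
                        stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  missing_cols <- setdiff(setdiff(COHORT_COLUMNS, c("log_mtv", "rece",
                                                    "cured_label")),
                          names(df))
  if (length(missing_cols))
    abort("cohort is missing required columns: %s", toString(missing_cols))
  if (strict) {
    extra <- setdiff(names(df), COHORT_COLUMNS)
    if (length(extra)) abort("unknown columns: %s", toString(extra))
  }
  for (v in c("sex", "ace27", "smoking", "p16", "ct", "cn"))
    df[[v]] <- match_levels(df[[v]], COVARIATE_LEVELS[[v]], v)
  for (v in intersect(c("anemia", "rece", "persistent", "cured_label"),
                      names(df)))
    df[[v]] <- as.logical(df[[v]])
  errs <- character()
  bad <- function(rows, what)
    if (length(rows))
      errs <<- c(errs, sprintf("rows %s: %s",
                               toString(utils::head(rows, 5)), what))
  bad(which(!(df$first_event %in% c("none", "lrr", "dm", "death"))),
      "first_event must be none/lrr/dm/death")
  bad(which(df$followup_time < 0 | df$recurrence_time < 0 |
              df$death_time < 0), "negative time")
  bad(which(df$recurrence_time > df$death_time),
      "recurrence_time after death_time")
  bad(which(df$persistent & df$first_event %in% c("lrr", "dm")),
      "persistent record with a recurrence transition")
  bad(which(df$first_event %in% c("lrr", "dm") &
              is.na(df$recurrence_time)),
      "recurrence without recurrence_time")
  bad(which(df$first_event == "death" & is.na(df$death_time)),
      "death event without death_time")
  if (length(errs))
    abort("invalid cohort:\n  %s", paste(errs, collapse = "\n  "))
  df
}

#' Run the full pipeline
#'
#' Simulates a cohort, fits the model, predicts occupancy for every patient
#' and validates the fit, writing each artifact to `out_dir`: `cohort.csv`
#' and `truth.csv`, `params_true.json` and `params_fit.json`,
#' `fit_summary.csv` (component/term/estimate/CrI), `calibration.csv` and
#' `validation.json`. All randomness flows from `seed`; outputs are written
#' atomically and re-running with the same configuration reproduces them.
#'
#' @param out_dir Output directory (created if needed).
#' @param n Cohort size.
#' @param seed Integer seed.
#' @param n_iter,burnin MCMC settings.
#' @param imaging Use the imaging-augmented formulation?
#' @param horizons Validation horizons (months).
#' @param progress Passed to [run_mcmc()].
#' @return Invisibly, a list with the in-memory artifacts.
#' @export
run_pipeline <- function(out_dir, n = 300, seed = 1, n_iter = 500,
                         burnin = 200, imaging = FALSE,
                         horizons = c(12, 36, 60), progress = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      abort("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  params <- reference_params(imaging = imaging)
  sim <- stage("simulate",
               generate_cohort(cohort_config(n = n, seed = seed), params))
  write_cohort(sim$cohort, file.path(out_dir, "cohort.csv"), seed = seed)
  write_atomic(function(tmp) utils::write.csv(sim$truth, tmp,
                                              row.names = FALSE),
               file.path(out_dir, "truth.csv"))
  write_params(params, file.path(out_dir, "params_true.json"))

  draws <- stage("fit", run_mcmc(sim$cohort,
                                 specs = component_specs(imaging = imaging),
                                 n_iter = n_iter, burnin = burnin,
                                 seed = seed + 1, progress = progress))
  fit_params <- posterior_mean_params(draws)
  write_params(fit_params, file.path(out_dir, "params_fit.json"))
  write_atomic(function(tmp) utils::write.csv(posterior_summary(draws), tmp,
                                              row.names = FALSE),
               file.path(out_dir, "fit_summary.csv"))

  completed <- if (length(draws$imputations)) draws$imputations[[
    length(draws$imputations)]] else sim$cohort
  report <- stage("validate",
                  validation_report(completed, fit_params,
                                    horizon = max(horizons),
                                    strata = "ct"))
  write_atomic(function(tmp) utils::write.csv(report$calibration, tmp,
                                              row.names = FALSE),
               file.path(out_dir, "calibration.csv"))
  write_atomic(function(tmp) jsonlite::write_json(
    list(seed = seed, n = n,
         auc_os_5yr = report$auc_os_5yr, auc_efs_5yr = report$auc_efs_5yr,
         c_index_os = report$c_index_os, c_index_efs = report$c_index_efs,
         cox_snell_slope = report$cox_snell$slope,
         cox_snell_pass = report$cox_snell$pass),
    tmp, auto_unbox = TRUE, digits = NA), file.path(out_dir,
                                                    "validation.json"))
  invisible(list(cohort = sim$cohort, truth = sim$truth, draws = draws,
                 params_fit = fit_params, report = report))
}
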