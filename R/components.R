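# Covariate metadata and per-component model specifications.
#
# The multistate model has eight components: two logistic models for the
# initial state (C1 persistent disease, C2 noncured given nonpersistent) and
# six proportional-hazards transition models (C3 locoregional recurrence,
# C4 distant metastasis, C5 death without prior recurrence, C6 death with
# persistent disease, C7 death after locoregional recurrence, C8 death after
# distant metastasis). C3/C4 use piecewise Weibull baselines with a change
# point at 6 months; C7/C8 run on a clock reset at recurrence.

COVARIATE_LEVELS <- list(
  sex     = c("male", "female"),
  ace27   = c("none", "mild", "moderate", "severe"),
  smoking = c("never", "former", "current"),
  p16     = c("positive", "negative"),
  ct      = c("T1", "T2", "T3", "T4"),
  cn      = c("N0", "N1", "N2abc", "N3")
)

COVARIATE_FIELDS <- c("age", "sex", "ace27", "smoking", "anemia", "p16",
                      "ct", "cn", "log_mtv", "rece")

# design columns contributed by each covariate (reference levels: male sex,
# ACE27 none, never smoker, no anemia, p16-positive, cT1, cN0/cN1, no rECE)
covariate_columns <- function(name, merge_n0n1 = TRUE) {
  switch(name,
    age     = "age_std",
    sex     = "sex_female",
    ace27   = c("ace27_mild", "ace27_moderate", "ace27_severe"),
    smoking = c("smoking_former", "smoking_current"),
    anemia  = "anemia",
    p16     = "p16_negative",
    ct      = c("ct_T2", "ct_T3", "ct_T4"),
    cn      = if (merge_n0n1) c("cn_N2abc", "cn_N3") else
                c("cn_N1", "cn_N2abc", "cn_N3"),
    log_mtv = "log_mtv_std",
    rece    = "rece",
    abort("unknown covariate '%s'", name)
  )
}

#' Component model specification
#'
#' Describes one of the eight component models: which covariates enter its
#' linear predictor, its baseline family, its change point (piecewise
#' components only) and whether its clock runs from baseline or from entry
#' into the origin state.
#'
#' @param id Component id, one of `"c1"` to `"c8"`.
#' @param covariates Character vector of covariate names (subset of
#'   `r toString(COVARIATE_FIELDS)`); may be empty.
#' @param baseline One of `"logistic"`, `"weibull"`, `"piecewise_weibull"`.
#' @param change_point Change point in months for piecewise baselines.
#' @param clock `"from_baseline"` or `"from_state_entry"`.
#' @param merge_n0n1 Should cN0 and cN1 share the reference level? Defaults
#'   to `TRUE` (the model's reference category is "cN0 or cN1").
#' @return An object of class `component_spec`.
#' @export
component_spec <- function(id, covariates, baseline,
                           change_point = NULL,
                           clock = "from_baseline",
                           merge_n0n1 = TRUE) {
  id <- match.arg(id, paste0("c", 1:8))
  baseline <- match.arg(baseline, c("logistic", "weibull", "piecewise_weibull"))
  clock <- match.arg(clock, c("from_baseline", "from_state_entry"))
  bad <- setdiff(covariates, COVARIATE_FIELDS)
  if (length(bad))
    abort("unknown covariates in %s: %s", id, toString(bad))
  if (baseline == "piecewise_weibull" && is.null(change_point))
    abort("piecewise baseline for %s needs a change point", id)
  if (baseline != "piecewise_weibull") change_point <- NULL
  structure(
    list(id = id, covariates = as.character(covariates), baseline = baseline,
         change_point = change_point, clock = clock, merge_n0n1 = merge_n0n1),
    class = "component_spec")
}

#' @export
print.component_spec <- function(x, ...) {
  cat(sprintf("<component_spec %s> %s baseline%s, clock %s\n  covariates: %s\n",
              x$id, x$baseline,
              if (!is.null(x$change_point))
                sprintf(" (change point %g mo)", x$change_point) else "",
              x$clock,
              if (length(x$covariates)) toString(x$covariates) else "(none)"))
  invisible(x)
}

#' Default component specifications
#'
#' Returns the list of eight `component_spec`s used throughout the package.
#' C1 and C2 are logistic models for the initial state; C3 and C4 are
#' piecewise Weibull transitions (change point at 6 months) to locoregional
#' recurrence and distant metastasis; C5-C8 are Weibull death transitions,
#' with C6 covariate-free (deaths with persistent disease occur quickly, so
#' no covariate effects are modelled) and C7/C8 on a clock reset at
#' recurrence.
#'
#' @param imaging If `TRUE`, the imaging markers (log metabolic tumor volume
#'   and radiologic extracapsular extension) enter C2, C3 and C4; with
#'   `FALSE` (default) the clinical-only formulation is returned.
#' @param merge_n0n1 Merge cN0/cN1 into one reference level (default `TRUE`).
#' @return Named list of `component_spec` objects, `c1` to `c8`.
#' @export
component_specs <- function(imaging = FALSE, merge_n0n1 = TRUE) {
  img <- if (imaging) c("log_mtv", "rece") else character()
  list(
    c1 = component_spec("c1", c("ace27", "ct", "p16"), "logistic",
                        merge_n0n1 = merge_n0n1),
    c2 = component_spec("c2",
                        c("age", "smoking", "anemia", "p16", "ct", "cn", img),
                        "logistic", merge_n0n1 = merge_n0n1),
    c3 = component_spec("c3", c("p16", "ct", "cn", if (imaging) "rece"),
                        "piecewise_weibull", change_point = 6,
                        merge_n0n1 = merge_n0n1),
    c4 = component_spec("c4", c("ct", "cn", if (imaging) "rece"),
                        "piecewise_weibull", change_point = 6,
                        merge_n0n1 = merge_n0n1),
    c5 = component_spec("c5", c("age", "sex", "ace27", "smoking", "anemia",
                                "p16"), "weibull", merge_n0n1 = merge_n0n1),
    c6 = component_spec("c6", character(), "weibull"),
    c7 = component_spec("c7", c("age", "p16"), "weibull",
                        clock = "from_state_entry", merge_n0n1 = merge_n0n1),
    c8 = component_spec("c8", c("age", "p16"), "weibull",
                        clock = "from_state_entry", merge_n0n1 = merge_n0n1)
  )
}

#' Classify anemia from hemoglobin
#'
#' Anemia is defined as hemoglobin below 12 g/dL for women and below 13 g/dL
#' for men (strict inequality at the threshold).
#'
#' @param hemoglobin_g_dl Hemoglobin in g/dL (vectorized).
#' @param sex `"male"` or `"female"` (recycled against hemoglobin).
#' @return Logical vector: `TRUE` if anemic.
#' @examples
#' classify_anemia(11.5, "female")  # TRUE
#' classify_anemia(13.5, "male")    # FALSE
#' @export
classify_anemia <- function(hemoglobin_g_dl, sex) {
  sex <- match_levels(sex, COVARIATE_LEVELS$sex, "sex")
  ok <- is.na(hemoglobin_g_dl) |
    (hemoglobin_g_dl > 0 & hemoglobin_g_dl <= 25)
  if (!all(ok))
    abort("implausible hemoglobin value(s): %s",
          toString(hemoglobin_g_dl[!ok]))
  thr <- ifelse(sex == "female", 12, 13)
  hemoglobin_g_dl < thr
}

# validate and normalize a categorical field against its level set
match_levels <- function(x, levels, field) {
  x <- as.character(x)
  bad <- !is.na(x) & !(x %in% levels)
  if (any(bad))
    abort("unknown %s level(s): %s (expected %s)",
          field, toString(unique(x[bad])), toString(levels))
  x
}

#' Encode covariates as a design matrix
#'
#' Dummy-codes the covariates named in a component spec against the model's
#' reference categories (male sex, no ACE27 comorbidity, never smoker, no
#' anemia, p16-positive, cT1, cN0/cN1, no rECE) and standardizes age and
#' log metabolic tumor volume using stored constants, so that predictions
#' are reproducible on new data. Missing values propagate as `NA` in every
#' column the covariate contributes; they are never silently zeroed.
#'
#' @param data Data frame (or single-row list) with raw covariate columns:
#'   `age` (years), `sex`, `ace27`, `smoking`, `anemia` (logical), `p16`,
#'   `ct`, `cn`, and optionally `log_mtv` (log mL) and `rece` (logical;
#'   equivocal findings should already be coded negative at ingestion).
#' @param spec A `component_spec` (or a character vector of covariate names).
#' @param standardization List with `age_mean`, `age_sd`, `mtv_mean`,
#'   `mtv_sd` used to z-score the continuous covariates.
#' @param merge_n0n1 Used only when `spec` is a character vector.
#' @return Numeric matrix with one row per row of `data`; zero columns when
#'   the covariate subset is empty.
#' @export
encode_covariates <- function(data, spec,
                              standardization = default_standardization(),
                              merge_n0n1 = TRUE) {
  if (inherits(spec, "component_spec")) {
    covs <- spec$covariates
    merge_n0n1 <- spec$merge_n0n1 %||% TRUE
  } else covs <- spec
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  n <- nrow(data)
  cols <- list()
  for (cv in covs) {
    missing_col <- !(cv %in% names(data))
    val <- if (missing_col) rep(NA, n) else data[[cv]]
    cols[[cv]] <- encode_one(cv, val, standardization, merge_n0n1)
  }
  if (!length(cols)) return(matrix(0, n, 0))
  do.call(cbind, cols)
}

encode_one <- function(name, x, std, merge_n0n1) {
  nm <- covariate_columns(name, merge_n0n1)
  if (name %in% c("age", "log_mtv")) {
    x <- as.numeric(x)
    out <- if (name == "age") (x - std$age_mean) / std$age_sd
           else (x - std$mtv_mean) / std$mtv_sd
    out <- matrix(out, ncol = 1)
  } else if (name %in% c("anemia", "rece")) {
    out <- matrix(as.numeric(as.logical(x)), ncol = 1)
  } else {
    lv <- COVARIATE_LEVELS[[name]]
    x <- match_levels(x, lv, name)
    if (name == "cn" && merge_n0n1)
      lv <- c("N0/N1", "N2abc", "N3")
    xx <- if (name == "cn" && merge_n0n1)
      ifelse(x %in% c("N0", "N1"), "N0/N1", x) else x
    out <- sapply(lv[-1], function(l) as.numeric(xx == l))
    if (!is.matrix(out)) out <- matrix(out, nrow = length(x))
    out[is.na(x), ] <- NA  # missing propagates to every dummy
  }
  colnames(out) <- nm
  out
}

#' Default standardization constants
#'
#' Centering/scaling constants for age (years) and log metabolic tumor
#' volume (log mL), chosen to match the training-cohort marginals (median
#' age 58, IQR 52-64.4; median MTV 13.6 mL, IQR 8.4-20.7).
#'
#' @return List with `age_mean`, `age_sd`, `mtv_mean`, `mtv_sd`.
#' @export
default_standardization <- function() {
  list(age_mean = 58, age_sd = 9.2,
       mtv_mean = log(13.6), mtv_sd = 0.67)
}
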