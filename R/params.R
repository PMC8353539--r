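# Parameter container for the eight-component multistate cure model, plus
# JSON (de)serialization and a realistic default parameter set used by the
# synthetic cohort generator.

#' Multistate model parameters
#'
#' Bundles the parameters of all eight component models with the component
#' specifications and standardization constants they were defined against.
#' C1/C2 carry an intercept and log-odds coefficients; C3/C4 carry two
#' Weibull segments (shape, scale per segment, change point fixed at 6
#' months) and log-hazard-ratio coefficients; C5-C8 carry one Weibull
#' (shape, scale) each, C6 with no coefficients.
#'
#' @param c1,c2 Lists with `intercept` (scalar) and `coef` (named numeric).
#' @param c3,c4 Lists with `shape1`, `scale1`, `shape2`, `scale2` (positive,
#'   scales in months) and `coef`.
#' @param c5,c7,c8 Lists with `shape`, `scale`, `coef`.
#' @param c6 List with `shape`, `scale` only.
#' @param specs Component specifications, as from [component_specs()].
#' @param standardization Constants from [default_standardization()].
#' @return An object of class `msm_params`.
#' @export
msm_params <- function(c1, c2, c3, c4, c5, c6, c7, c8,
                       specs = component_specs(),
                       standardization = default_standardization()) {
  p <- structure(list(c1 = c1, c2 = c2, c3 = c3, c4 = c4, c5 = c5,
                      c6 = c6, c7 = c7, c8 = c8),
                 specs = specs, standardization = standardization,
                 class = "msm_params")
  p$c3$change_point <- specs$c3$change_point
  p$c4$change_point <- specs$c4$change_point
  p$c6$coef <- numeric(0)
  validate_params(p)
  p
}

params_specs <- function(params) attr(params, "specs")
params_std   <- function(params) attr(params, "standardization")

validate_params <- function(p) {
  specs <- params_specs(p)
  for (id in paste0("c", 1:8)) {
    comp <- p[[id]]
    spec <- specs[[id]]
    want <- unlist(lapply(spec$covariates, covariate_columns,
                          merge_n0n1 = spec$merge_n0n1 %||% TRUE))
    if (is.null(want)) want <- character()
    have <- names(comp$coef) %||% character()
    if (length(comp$coef) != length(want) ||
        (length(want) && !identical(have, want)))
      abort("%s coefficients must be named %s", id,
            if (length(want)) toString(want) else "(empty)")
    pos <- if (id %in% c("c3", "c4"))
      unlist(comp[c("shape1", "scale1", "shape2", "scale2")])
    else if (id %in% c("c5", "c6", "c7", "c8"))
      unlist(comp[c("shape", "scale")])
    else numeric()
    if (any(!is.finite(pos)) || any(pos <= 0))
      abort("%s baseline parameters must be positive and finite", id)
  }
  invisible(p)
}

#' @export
print.msm_params <- function(x, ...) {
  cat("<msm_params> 8-component multistate cure model\n")
  for (id in paste0("c", 1:8)) {
    comp <- x[[id]]
    base <- if (!is.null(comp$intercept))
      sprintf("intercept % .3f", comp$intercept)
    else if (!is.null(comp$change_point))
      sprintf("Weibull segs (%.2f,%.1f)/(%.2f,%.1f), cp %g mo",
              comp$shape1, comp$scale1, comp$shape2, comp$scale2,
              comp$change_point)
    else sprintf("Weibull (%.2f, %.1f)", comp$shape, comp$scale)
    cat(sprintf("  %s: %s; %d coefficient(s)\n", id, base,
                length(comp$coef)))
  }
  invisible(x)
}

named <- function(values, names) stats::setNames(values, names)

comp_cols <- function(spec) {
  out <- unlist(lapply(spec$covariates, covariate_columns,
                       merge_n0n1 = spec$merge_n0n1 %||% TRUE))
  if (is.null(out)) character() else out
}

# zero-coefficient parameter skeleton for a given spec set
null_params <- function(specs = component_specs(),
                        standardization = default_standardization()) {
  zero <- function(spec) named(rep(0, length(comp_cols(spec))),
                               comp_cols(spec))
  msm_params(
    c1 = list(intercept = 0, coef = zero(specs$c1)),
    c2 = list(intercept = 0, coef = zero(specs$c2)),
    c3 = list(shape1 = 1, scale1 = 50, shape2 = 1, scale2 = 50,
              coef = zero(specs$c3)),
    c4 = list(shape1 = 1, scale1 = 50, shape2 = 1, scale2 = 50,
              coef = zero(specs$c4)),
    c5 = list(shape = 1, scale = 100, coef = zero(specs$c5)),
    c6 = list(shape = 1, scale = 12),
    c7 = list(shape = 1, scale = 30, coef = zero(specs$c7)),
    c8 = list(shape = 1, scale = 20, coef = zero(specs$c8)),
    specs = specs, standardization = standardization)
}

#' Reference parameter set for simulation
#'
#' A fixed, realistic parameter set for the clinical-only (or, with
#' `imaging = TRUE`, imaging-augmented) model formulation. Signs and rough
#' magnitudes follow the fitted-model pattern for this disease: persistent
#' disease is more likely with severe comorbidity, cT4 and p16-negative
#' tumors; noncure is more likely with age, smoking, anemia, p16-negative
#' status and advanced cT/cN; locoregional recurrence hazard is higher for
#' p16-negative tumors and lower for higher cT/cN (which shift risk toward
#' metastasis); metastasis hazard increases in cN; post-persistence death is
#' fast (median under a year); post-recurrence death is faster after
#' metastasis than after locoregional recurrence. Baseline scales are in
#' months. Used as generating truth by [generate_cohort()] and in examples.
#'
#' @param imaging Include logMTV/rECE effects (odds ratio 1.65 and 3.67 in
#'   C2; rECE hazard ratios 2.42 in C3 and 5.11 in C4)?
#' @return An [msm_params] object.
#' @export
reference_params <- function(imaging = FALSE) {
  specs <- component_specs(imaging = imaging)
  img2 <- if (imaging) named(c(log(1.65), log(3.67)),
                             c("log_mtv_std", "rece")) else NULL
  img3 <- if (imaging) named(log(2.42), "rece") else NULL
  img4 <- if (imaging) named(log(5.11), "rece") else NULL
  msm_params(
    c1 = list(intercept = -4.4,
              coef = named(c(0.25, 0.5, 0.9, 0.3, 0.6, 1.1, 0.9),
                           comp_cols(specs$c1))),
    c2 = list(intercept = -2.0,
              coef = c(named(c(0.25, 0.35, 0.7, 0.45, 0.9,
                               0.3, 0.55, 0.8, 0.45, 0.75),
                             setdiff(comp_cols(specs$c2), names(img2))),
                       img2)),
    c3 = list(shape1 = 1.3, scale1 = 50, shape2 = 0.85, scale2 = 60,
              coef = c(named(c(0.9, -0.25, -0.45, -0.65, -0.3, -0.5),
                             setdiff(comp_cols(specs$c3), names(img3))),
                       img3)),
    c4 = list(shape1 = 1.3, scale1 = 70, shape2 = 0.9, scale2 = 170,
              coef = c(named(c(0.2, 0.35, 0.5, 0.55, 1.0),
                             setdiff(comp_cols(specs$c4), names(img4))),
                       img4)),
    c5 = list(shape = 1.1, scale = 1100,
              coef = named(c(0.45, -0.15, 0.35, 0.65, 1.0, 0.3, 0.6,
                             0.4, 0.5),
                           comp_cols(specs$c5))),
    c6 = list(shape = 0.95, scale = 14),
    c7 = list(shape = 1.0, scale = 50,
              coef = named(c(0.25, 0.5), comp_cols(specs$c7))),
    c8 = list(shape = 1.1, scale = 20,
              coef = named(c(0.2, 0.3), comp_cols(specs$c8))),
    specs = specs)
}

#' Write model parameters to JSON
#'
#' Serializes an [msm_params] object (component blocks `c1`-`c8` with named
#' coefficients, component specifications and standardization constants) to
#' a JSON document.
#'
#' @param params An [msm_params] object.
#' @param path File path to write.
#' @export
write_params <- function(params, path) {
  specs <- params_specs(params)
  doc <- list(
    components = lapply(params, function(comp) {
      comp$coef <- as.list(comp$coef %||% numeric())
      comp
    }),
    specs = lapply(specs, function(s) unclass(s)),
    standardization = params_std(params))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read model parameters from JSON
#'
#' @param path Path to a JSON file written by [write_params()].
#' @return An [msm_params] object.
#' @export
read_params <- function(path) {
  doc <- jsonlite::read_json(path)
  specs <- lapply(doc$specs, function(s)
    component_spec(s$id, unlist(s$covariates) %||% character(), s$baseline,
                   change_point = s$change_point,
                   clock = s$clock %||% "from_baseline",
                   merge_n0n1 = s$merge_n0n1 %||% TRUE))
  comps <- lapply(doc$components, function(comp) {
    comp$coef <- unlist(comp$coef) %||% numeric()
    comp
  })
  do.call(msm_params, c(comps[paste0("c", 1:8)],
                        list(specs = specs,
                             standardization = doc$standardization)))
}

# --- flat parameter vector view used by the sampler ----------------------

# baseline parameters are sampled on the log scale
flatten_params <- function(p) {
  out <- c()
  for (id in paste0("c", 1:8)) {
    comp <- p[[id]]
    base <- if (!is.null(comp$intercept)) named(comp$intercept, "intercept")
    else if (!is.null(comp$change_point))
      named(log(c(comp$shape1, comp$scale1, comp$shape2, comp$scale2)),
            c("log_shape1", "log_scale1", "log_shape2", "log_scale2"))
    else named(log(c(comp$shape, comp$scale)), c("log_shape", "log_scale"))
    v <- c(base, comp$coef)
    if (length(v)) names(v) <- paste0(id, ".", names(v))
    out <- c(out, v)
  }
  out
}

unflatten_params <- function(theta, template) {
  p <- template
  for (id in paste0("c", 1:8)) {
    comp <- p[[id]]
    pick <- function(nm) unname(theta[paste0(id, ".", nm)])
    if (!is.null(comp$intercept)) {
      p[[id]]$intercept <- pick("intercept")
    } else if (!is.null(comp$change_point)) {
      p[[id]]$shape1 <- exp(pick("log_shape1"))
      p[[id]]$scale1 <- exp(pick("log_scale1"))
      p[[id]]$shape2 <- exp(pick("log_shape2"))
      p[[id]]$scale2 <- exp(pick("log_scale2"))
    } else {
      p[[id]]$shape <- exp(pick("log_shape"))
      p[[id]]$scale <- exp(pick("log_scale"))
    }
    if (length(comp$coef))
      p[[id]]$coef <- named(theta[paste0(id, ".", names(comp$coef))],
                            names(comp$coef))
  }
  p
}
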