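#' Covariate terms on apparent clearance
#'
#' Constructors for the covariate sub-models tested on CL/F. Continuous
#' covariates are centred at a reference value so that the typical-value
#' parameter `theta_cl` keeps its interpretation as the clearance of a
#' reference child; categorical covariates act as multiplicative factors
#' relative to a reference level (wild type for genotypes).
#'
#' Forms, for covariate value `x` with reference `ref` and coefficient
#' `theta`:
#' * power: `(x / ref)^theta`
#' * linear: `1 + theta * (x - ref)` (floored at a small positive value so a
#'   trial coefficient during estimation cannot drive clearance negative)
#' * exponential: `exp(theta * (x - ref))`
#' * piecewise: two linear slopes, below and above `ref` (2 coefficients)
#' * multiplier: one factor per non-reference level, reference fixed at 1
#'
#' @param name covariate column name in the dataset (e.g. `"AGE"`,
#'   `"rs3789243"`).
#' @param theta coefficient (dimensionless for power/exponential; per unit of
#'   the covariate for linear).
#' @param ref reference (centering) value of a continuous covariate, in its
#'   own units.
#' @param theta_low,theta_high slopes below/above `ref` for the piecewise
#'   form.
#' @param ref_level reference level of a categorical covariate.
#' @param multipliers named positive vector of factors for each
#'   non-reference level.
#' @return An object of class `vpa_covterm`.
#' @examples
#' cov_power("AGE", theta = 0.357, ref = 5)
#' cov_multiplier("rs3789243", ref_level = "AA",
#'                multipliers = c(AG = 0.953, GG = 1.08))
#' @name covterms
NULL

new_covterm <- function(name, form, coef, ref = NULL, ref_level = NULL,
                        levels = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  structure(
    list(covariate = name, form = form, coef = coef, ref = ref,
         ref_level = ref_level, levels = levels),
    class = "vpa_covterm"
  )
}

#' @rdname covterms
#' @export
cov_power <- function(name, theta = 0, ref) {
  stopifnot(is.numeric(ref), ref > 0)
  new_covterm(name, "power", c(theta = theta), ref = ref)
}

#' @rdname covterms
#' @export
cov_linear <- function(name, theta = 0, ref) {
  new_covterm(name, "linear", c(theta = theta), ref = ref)
}

#' @rdname covterms
#' @export
cov_exponential <- function(name, theta = 0, ref) {
  new_covterm(name, "exponential", c(theta = theta), ref = ref)
}

#' @rdname covterms
#' @export
cov_piecewise <- function(name, theta_low = 0, theta_high = 0, ref) {
  new_covterm(name, "piecewise",
              c(theta_low = theta_low, theta_high = theta_high), ref = ref)
}

#' @rdname covterms
#' @export
cov_multiplier <- function(name, ref_level, multipliers) {
  stopifnot(length(multipliers) >= 1L, all(multipliers > 0),
            !is.null(names(multipliers)), !ref_level %in% names(multipliers))
  new_covterm(name, "multiplier", multipliers, ref_level = ref_level,
              levels = c(ref_level, names(multipliers)))
}

#' @export
print.vpa_covterm <- function(x, ...) {
  if (x$form == "multiplier") {
    cat(sprintf("<%s on CL/F: ref %s; %s>\n", x$covariate, x$ref_level,
                paste(sprintf("%s=%.4g", names(x$coef), x$coef),
                      collapse = ", ")))
  } else {
    cat(sprintf("<%s on CL/F: %s, ref %.4g; %s>\n", x$covariate, x$form,
                x$ref,
                paste(sprintf("%s=%.4g", names(x$coef), x$coef),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Residual-error models
#'
#' Residual variability of an observed trough around its model prediction
#' `f`: additive (`sd = sigma_add`, mg/L), proportional
#' (`sd = sigma_prop * f`), or combined
#' (`sd = sqrt(sigma_add^2 + (sigma_prop * f)^2)`).
#'
#' @param kind one of `"additive"`, `"proportional"`, `"combined"`.
#' @param sigma_add additive standard deviation (mg/L).
#' @param sigma_prop proportional standard deviation (dimensionless CV).
#' @return An object of class `vpa_error`.
#' @export
vpa_error <- function(kind = c("additive", "proportional", "combined"),
                      sigma_add = NULL, sigma_prop = NULL) {
  kind <- match.arg(kind)
  if (kind %in% c("additive", "combined")) {
    stopifnot(is.numeric(sigma_add), sigma_add >= 0)
  } else sigma_add <- NULL
  if (kind %in% c("proportional", "combined")) {
    stopifnot(is.numeric(sigma_prop), sigma_prop >= 0)
  } else sigma_prop <- NULL
  structure(list(kind = kind, sigma_add = sigma_add,
                 sigma_prop = sigma_prop),
            class = "vpa_error")
}

resid_sd <- function(error, f) {
  switch(error$kind,
         additive = rep_len(error$sigma_add, length(f)),
         proportional = error$sigma_prop * abs(f),
         combined = sqrt(error$sigma_add^2 + (error$sigma_prop * f)^2))
}

#' Hierarchical population-PK model specification
#'
#' A one-compartment oral model at steady state with covariate-dependent
#' apparent clearance, a log-normal inter-individual random effect on CL/F,
#' and a residual-error model. The absorption rate constant `ka` is fixed
#' (trough-only data carry no absorption information) and bioavailability is
#' absorbed into the apparent (`/F`) parameterization.
#'
#' Typical clearance of a subject is
#' `CL/F = theta_cl * prod(covariate effects)`, individual clearance
#' `CL_i = CL/F * exp(eta)` with `eta ~ N(0, omega_cl^2)`.
#'
#' @param theta_cl typical apparent clearance (L/h) at the covariate
#'   reference point.
#' @param theta_v typical apparent volume of distribution (L).
#' @param ka first-order absorption rate constant (1/h); fixed, never
#'   estimated.
#' @param covariates list of [cov_power()]-style terms acting on CL/F.
#' @param omega_cl standard deviation of the log-scale random effect on
#'   CL/F (approximately the CV of clearance).
#' @param error a [vpa_error()] residual model.
#' @return An object of class `vpa_model`.
#' @examples
#' vpa_final_model()
#' @export
vpa_model <- function(theta_cl, theta_v, ka = 1.9, covariates = list(),
                      omega_cl = 0, error = vpa_error("additive",
                                                      sigma_add = 1)) {
  stopifnot(theta_cl > 0, theta_v > 0, ka > 0, omega_cl >= 0,
            inherits(error, "vpa_error"))
  stopifnot(all(vapply(covariates, inherits, TRUE, "vpa_covterm")))
  nm <- vapply(covariates, `[[`, "", "covariate")
  if (anyDuplicated(nm)) stop("duplicate covariate terms: ",
                              paste(nm[duplicated(nm)], collapse = ", "))
  structure(list(theta_cl = theta_cl, theta_v = theta_v, ka = ka,
                 covariates = covariates, omega_cl = omega_cl,
                 error = error),
            class = "vpa_model")
}

#' @export
print.vpa_model <- function(x, ...) {
  cat("One-compartment oral steady-state population-PK model\n")
  cat(sprintf("  theta_cl = %.4g L/h, theta_v = %.4g L, ka = %.3g 1/h (fixed)\n",
              x$theta_cl, x$theta_v, x$ka))
  for (ct in x$covariates) {
    cat("  "); print(ct)
  }
  cat(sprintf("  omega_cl = %.4g (log-scale SD)\n", x$omega_cl))
  e <- x$error
  cat(sprintf("  residual: %s (%s)\n", e$kind,
              paste(c(if (!is.null(e$sigma_add))
                        sprintf("sigma_add = %.4g mg/L", e$sigma_add),
                      if (!is.null(e$sigma_prop))
                        sprintf("sigma_prop = %.4g", e$sigma_prop)),
                    collapse = ", ")))
  invisible(x)
}

#' Published-model convenience constructors
#'
#' `vpa_final_model()` returns the age- and ABCB1 rs3789243-adjusted final
#' model for pediatric valproic acid: typical clearance 0.214 L/h for a
#' 5-year-old rs3789243 AA child, an age effect `(AGE/5)^0.357`, multipliers
#' 0.953 (AG) and 1.08 (GG), typical volume 3.63 L, inter-individual SD
#' 0.169 on log-clearance, and additive residual SD 11.9 mg/L.
#' `vpa_base_model()` is the covariate-free base model (0.205 L/h, 3.43 L,
#' omega 0.302, sigma 13.7 mg/L).
#'
#' @param age_ref reference age in years for the age power term.
#' @return A [vpa_model()].
#' @export
vpa_final_model <- function(age_ref = 5) {
  vpa_model(theta_cl = 0.214, theta_v = 3.63, ka = 1.9,
            covariates = list(
              cov_power("AGE", theta = 0.357, ref = age_ref),
              cov_multiplier("rs3789243", ref_level = "AA",
                             multipliers = c(AG = 0.953, GG = 1.08))),
            omega_cl = 0.169,
            error = vpa_error("additive", sigma_add = 11.9))
}

#' @rdname vpa_final_model
#' @export
vpa_base_model <- function() {
  vpa_model(theta_cl = 0.205, theta_v = 3.43, ka = 1.9,
            omega_cl = 0.302,
            error = vpa_error("additive", sigma_add = 13.7))
}

# Evaluate one covariate term on a vector of covariate values (continuous)
# or labels (categorical). Returns a positive multiplicative effect per row.
covterm_effect <- function(term, x) {
  switch(term$form,
    power = {
      if (any(x <= 0)) stop("power covariate ", term$covariate,
                            " requires positive values")
      (x / term$ref)^term$coef[["theta"]]
    },
    linear = pmax(1 + term$coef[["theta"]] * (x - term$ref), 1e-3),
    exponential = exp(term$coef[["theta"]] * (x - term$ref)),
    piecewise = {
      d <- x - term$ref
      eff <- 1 + ifelse(d < 0, term$coef[["theta_low"]],
                        term$coef[["theta_high"]]) * d
      pmax(eff, 1e-3)
    },
    multiplier = {
      x <- as.character(x)
      known <- c(term$ref_level, names(term$coef))
      bad <- setdiff(unique(x), known)
      if (length(bad) > 0) {
        stop(sprintf("unknown genotype/level '%s' for %s (expected %s)",
                     bad[1], term$covariate, paste(known, collapse = "/")))
      }
      mult <- c(1, unname(term$coef))[match(x, known)]
      mult
    },
    stop("unknown covariate form: ", term$form))
}

#' Typical (population) apparent clearance
#'
#' Evaluates the covariate model for CL/F on each row of a dataset (or any
#' data frame carrying the covariate columns): `theta_cl` times the product
#' of all covariate effects. A subject at every covariate reference (e.g. a
#' 5-year-old with the rs3789243 AA genotype under the final model) has
#' clearance exactly `theta_cl`.
#'
#' @param model a [vpa_model()].
#' @param data data frame with one column per model covariate.
#' @return Numeric vector of typical CL/F values (L/h), one per row.
#' @examples
#' m <- vpa_final_model()
#' typical_clearance(m, data.frame(AGE = 5, rs3789243 = "AA"))   # 0.214
#' typical_clearance(m, data.frame(AGE = 5, rs3789243 = "GG"))   # 0.214*1.08
#' @export
typical_clearance <- function(model, data) {
  stopifnot(inherits(model, "vpa_model"), is.data.frame(data))
  cl <- rep_len(model$theta_cl, nrow(data))
  for (term in model$covariates) {
    if (!term$covariate %in% names(data)) {
      stop("covariate column missing from data: ", term$covariate)
    }
    cl <- cl * covterm_effect(term, data[[term$covariate]])
  }
  cl
}

#' Individual apparent clearance
#'
#' Applies the log-normal inter-individual random effect:
#' `CL_i = typical_cl * exp(eta)`.
#'
#' @param typical_cl positive typical clearance (L/h).
#' @param eta subject-level random effect (log scale).
#' @return Individual clearance (L/h), strictly positive and increasing in
#'   `eta`.
#' @export
individual_clearance <- function(typical_cl, eta) {
  stopifnot(all(typical_cl > 0))
  typical_cl * exp(eta)
}
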