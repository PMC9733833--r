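# Dataset and result serialization. The dataset is a NONMEM-style flat
# file: one CSV row per steady-state trough, subject covariates repeated.

dataset_required_cols <- c("ID", "AGE", "WT", "SEX", "DOSE_MG", "II_H",
                           "TIME_H", "DV")

#' Read a long-format trough dataset
#'
#' Comma-separated, UTF-8, header required, `.` decimal, empty fields as
#' missing. Required columns: `ID`, `AGE`, `WT`, `SEX`, `DOSE_MG`, `II_H`,
#' `TIME_H`, `DV`; any further columns (genotypes, co-medication flags)
#' are carried through as covariates. Genotype labels of SNP columns that
#' appear in the package panel ([vpa_snp_counts()]) are validated against
#' the panel's declared genotypes, with row-level diagnostics. Quantified
#' concentrations below the assay's 1 mg/L lower limit of quantification
#' trigger a warning.
#'
#' @param path CSV file.
#' @param lloq lower limit of quantification (mg/L).
#' @return Validated data frame in row order.
#' @export
read_vpa_dataset <- function(path, lloq = 1) {
  data <- utils::read.csv(path, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  validate_vpa_dataset(data, lloq = lloq)
}

#' @rdname read_vpa_dataset
#' @param data in-memory dataset to validate without reading a file.
#' @export
validate_vpa_dataset <- function(data, lloq = 1) {
  miss <- setdiff(dataset_required_cols, names(data))
  if (length(miss)) stop("missing required column(s): ",
                         paste(miss, collapse = ", "))
  for (cc in c("AGE", "WT", "DOSE_MG", "II_H", "TIME_H", "DV")) {
    if (!is.numeric(data[[cc]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(data[[cc]]))) &
                     !is.na(data[[cc]]))
      stop(sprintf("column %s is not numeric (e.g. row %s)", cc,
                   paste(utils::head(bad, 3), collapse = ", ")))
    }
  }
  if (any(data$AGE <= 0) || any(data$WT <= 0)) {
    stop("AGE and WT must be strictly positive")
  }
  obs <- !is.na(data$DV)
  if (any(data$DOSE_MG[obs] <= 0) || any(data$II_H[obs] <= 0)) {
    stop("observation rows need positive DOSE_MG and II_H")
  }
  panel <- tryCatch(vpa_snp_counts(), error = function(e) NULL)
  if (!is.null(panel)) {
    for (s in intersect(panel$snp_id, names(data))) {
      labs <- strsplit(panel$genotype_labels[panel$snp_id == s],
                       "/", fixed = TRUE)[[1]]
      bad <- which(!is.na(data[[s]]) & !data[[s]] %in% labs)
      if (length(bad)) {
        stop(sprintf(
          "unknown genotype label '%s' for %s at row %d (expected %s)",
          data[[s]][bad[1]], s, bad[1], paste(labs, collapse = "/")))
      }
    }
  }
  n_low <- sum(data$DV[obs] < lloq)
  if (n_low > 0) {
    warning(sprintf(
      "%d observation(s) below the assay lower limit of quantification (%g mg/L)",
      n_low, lloq), call. = FALSE)
  }
  data
}

#' Write a long-format trough dataset
#'
#' @param data dataset (validated on the way out).
#' @param path destination CSV.
#' @return `path`, invisibly.
#' @export
write_vpa_dataset <- function(data, path) {
  validate_vpa_dataset(data)
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8", na = "")
  invisible(path)
}

covterm_to_list <- function(ct) {
  list(covariate = ct$covariate, form = ct$form,
       coef = as.list(ct$coef), ref = ct$ref, ref_level = ct$ref_level)
}

covterm_from_list <- function(x) {
  cf <- unlist(x$coef)
  switch(x$form,
         power = cov_power(x$covariate, cf[["theta"]], x$ref),
         linear = cov_linear(x$covariate, cf[["theta"]], x$ref),
         exponential = cov_exponential(x$covariate, cf[["theta"]], x$ref),
         piecewise = cov_piecewise(x$covariate, cf[["theta_low"]],
                                   cf[["theta_high"]], x$ref),
         multiplier = cov_multiplier(x$covariate, x$ref_level, cf),
         stop("unknown covariate form in document: ", x$form))
}

#' Serialize a fit to JSON
#'
#' Writes the model specification (thetas, covariate terms, omega, the
#' residual model, the fixed ka) plus OFV/AIC/BIC, RSEs, shrinkages,
#' convergence flag and software version. Numbers are serialized with 12
#' significant digits so that read-write round trips are value-identical.
#'
#' @param fit a [vpa_fit()].
#' @param path destination JSON file.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "vpa_fit"))
  m <- fit$model
  doc <- list(
    software = "vpapk",
    version = as.character(utils::packageVersion("vpapk")),
    model = list(
      theta_cl = m$theta_cl, theta_v = m$theta_v, ka = m$ka,
      covariates = lapply(m$covariates, covterm_to_list),
      omega_cl = m$omega_cl,
      error = list(kind = m$error$kind, sigma_add = m$error$sigma_add,
                   sigma_prop = m$error$sigma_prop)),
    fit = list(
      estimates = as.list(fit$estimates),
      se = as.list(fit$se),
      rse_pct = as.list(fit$rse_pct),
      ofv = fit$ofv, aic = fit$aic, bic = fit$bic,
      n_params = fit$n_params,
      eta_shrinkage_pct = fit$eta_shrinkage_pct,
      eps_shrinkage_pct = fit$eps_shrinkage_pct,
      converged = fit$converged,
      n_subjects = fit$n_subjects, n_obs = fit$n_obs,
      engine = fit$engine, nodes = fit$nodes))
  doc <- rapply(doc, function(x) if (is.numeric(x)) signif(x, 12) else x,
                how = "replace")
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a serialized fit document
#'
#' Reconstructs the [vpa_model()] and returns the stored fit summary.
#'
#' @param path JSON file written by [write_fit_json()].
#' @return List with `model` (a [vpa_model()]) and `fit` (the stored
#'   scalar summaries and named vectors).
#' @export
read_fit_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  md <- doc$model
  err <- vpa_error(md$error$kind,
                   sigma_add = md$error$sigma_add,
                   sigma_prop = md$error$sigma_prop)
  model <- vpa_model(theta_cl = md$theta_cl, theta_v = md$theta_v,
                     ka = md$ka,
                     covariates = lapply(md$covariates,
                                         covterm_from_list),
                     omega_cl = md$omega_cl, error = err)
  ft <- doc$fit
  num <- function(x) {
    if (is.null(x)) return(NULL)
    vapply(x, function(v) if (is.null(v)) NA_real_ else as.numeric(v), 0)
  }
  list(model = model,
       fit = list(estimates = num(ft$estimates), se = num(ft$se),
                  rse_pct = num(ft$rse_pct), ofv = ft$ofv, aic = ft$aic,
                  bic = ft$bic, n_params = ft$n_params,
                  eta_shrinkage_pct = ft$eta_shrinkage_pct,
                  eps_shrinkage_pct = ft$eps_shrinkage_pct,
                  converged = ft$converged,
                  n_subjects = ft$n_subjects, n_obs = ft$n_obs,
                  engine = ft$engine, nodes = ft$nodes))
}
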