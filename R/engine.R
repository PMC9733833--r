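# Marginal-likelihood machinery for the one-random-effect hierarchical model.
#
# Only clearance carries a random effect, so the per-subject marginal
# likelihood is a 1-D integral over eta. The reference engine evaluates it
# by adaptive Gauss-Hermite quadrature centred at the conditional mode with
# curvature-matched scaling; a FOCE-I style linearized engine is provided
# for comparison with the classical first-order conditional approximation.

.gh_cache <- new.env(parent = emptyenv())

gh_nodes <- function(n) {
  key <- as.character(n)
  if (is.null(.gh_cache[[key]])) .gh_cache[[key]] <- pracma::gaussHermite(n)
  .gh_cache[[key]]
}

#' Prepare a long-format dataset for estimation
#'
#' Validates and indexes a long-format trough dataset (one row per
#' observation, subject-level covariates repeated on each row). Rows with
#' missing `DV` are kept as design rows but excluded from the likelihood,
#' so a subject with no quantified observations still receives an empirical
#' Bayes estimate (the prior mode, 0).
#'
#' @param data data frame with at least `ID`, `DOSE_MG`, `II_H`, `TIME_H`,
#'   `DV`.
#' @return An opaque list used by the estimation functions.
#' @keywords internal
prepare_dataset <- function(data) {
  need <- c("ID", "DOSE_MG", "II_H", "TIME_H", "DV")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("dataset lacks required columns: ",
                         paste(miss, collapse = ", "))
  ids <- unique(data$ID)
  subj_of_row <- match(data$ID, ids)
  ok <- !is.na(data$DV)
  if (any(data$DOSE_MG[ok] <= 0)) stop("observation rows require DOSE_MG > 0")
  if (any(data$II_H[ok] <= 0)) stop("observation rows require II_H > 0")
  if (any(data$TIME_H[ok] <= 0 | data$TIME_H[ok] > data$II_H[ok])) {
    stop("TIME_H must lie in (0, II_H] on observation rows")
  }
  list(data = data,
       cache = new.env(parent = emptyenv()),
       ids = ids,
       n_subj = length(ids),
       n_obs = sum(ok),
       row_subj = subj_of_row,
       ok = ok,
       idx = subj_of_row[ok],
       present = sort(unique(subj_of_row[ok])),
       y = data$DV[ok],
       dose = data$DOSE_MG[ok],
       tau = data$II_H[ok],
       tt = data$TIME_H[ok])
}

# Typical clearance on the likelihood rows only.
cl_typ_rows <- function(model, prep) {
  cl <- rep_len(model$theta_cl, prep$n_obs)
  for (term in model$covariates) {
    x <- prep$data[[term$covariate]]
    if (is.null(x)) stop("covariate column missing from data: ",
                         term$covariate)
    cl <- cl * covterm_effect(term, x[prep$ok])
  }
  cl
}

# Per-subject components of the marginal log-likelihood. Returns the
# log-likelihood vector plus the conditional modes and curvatures that the
# EBE, shrinkage and CWRES computations reuse.
loglik_components <- function(model, prep, engine = c("agq", "foce"),
                              nodes = 21) {
  engine <- match.arg(engine)
  omega <- model$omega_cl
  err <- model$error
  if (err$kind %in% c("additive", "combined") && err$sigma_add <= 0 ||
      err$kind %in% c("proportional", "combined") && err$sigma_prop <= 0) {
    stop("residual standard deviations must be strictly positive")
  }
  ns <- prep$n_subj
  idx <- prep$idx
  y <- prep$y
  v <- model$theta_v
  ka <- model$ka
  cl_typ <- cl_typ_rows(model, prep)

  fconc <- function(eta_subj) {
    conc_ss_(prep$dose, prep$tau, prep$tt, cl_typ * exp(eta_subj[idx]), v, ka)
  }
  # negative log joint density per subject (data term + eta prior)
  half_l2pi <- 0.5 * log(2 * pi)
  sum_by_subj <- function(po) {
    out <- numeric(ns)
    rs <- rowsum(po, idx, reorder = TRUE)
    out[prep$present] <- rs[, 1L]
    out
  }
  data_neglog <- function(eta_subj) {
    f <- fconc(eta_subj)
    sd <- resid_sd(err, f)
    sum_by_subj(half_l2pi + log(sd) + 0.5 * ((y - f) / sd)^2)
  }

  if (omega == 0) {
    ll <- -data_neglog(numeric(ns))
    return(list(loglik = ll, eta_hat = numeric(ns),
                curvature = rep(Inf, ns), engine = "degenerate"))
  }

  prior_const <- 0.5 * log(2 * pi * omega^2)
  hpen <- function(eta_subj) {
    data_neglog(eta_subj) + prior_const + 0.5 * eta_subj^2 / omega^2
  }

  # vectorized damped Newton for the conditional modes of all subjects,
  # warm-started from the previous evaluation during optimization
  dh <- 1e-4
  eta <- numeric(ns)
  if (!is.null(prep$cache$eta) && length(prep$cache$eta) == ns) {
    eta <- prep$cache$eta
  }
  g <- numeric(ns)
  curv <- rep(1 / omega^2, ns)
  for (it in 1:60) {
    h0 <- hpen(eta)
    hp <- hpen(eta + dh)
    hm <- hpen(eta - dh)
    g <- (hp - hm) / (2 * dh)
    curv <- pmax((hp - 2 * h0 + hm) / dh^2, 1e-6)
    step <- pmin(pmax(-g / curv, -1), 1)
    eta <- eta + step
    if (max(abs(step)) < 1e-10) break
  }
  bad <- which(abs(g) > 1e-5)
  for (j in bad) {
    # rare fallback: scalar golden-section search for an awkward subject
    hj <- function(e) {
      ej <- eta
      ej[j] <- e
      hpen(ej)[j]
    }
    eta[j] <- stats::optimize(hj, c(eta[j] - 4, eta[j] + 4),
                              tol = 1e-10)$minimum
    curv[j] <- max((hj(eta[j] + dh) - 2 * hj(eta[j]) + hj(eta[j] - dh)) /
                     dh^2, 1e-6)
  }
  prep$cache$eta <- eta

  if (engine == "agq") {
    gh <- gh_nodes(nodes)
    s <- 1 / sqrt(curv)
    amat <- matrix(0, ns, nodes)
    for (k in seq_len(nodes)) {
      amat[, k] <- log(gh$w[k]) + gh$x[k]^2 -
        hpen(eta + sqrt(2) * s * gh$x[k])
    }
    amax <- apply(amat, 1, max)
    ll <- log(sqrt(2) * s) + amax + log(rowSums(exp(amat - amax)))
  } else {
    # FOCE-I: linearize f around the conditional mode; marginal covariance
    # V_j = G omega^2 G' + diag(sd^2) handled by rank-1 Woodbury identities.
    ipred <- fconc(eta)
    gvec <- (fconc(eta + dh) - fconc(eta - dh)) / (2 * dh)
    sd_i <- resid_sd(err, ipred)
    r <- y - (ipred - gvec * eta[idx])
    d <- sd_i^2
    s1 <- sum_by_subj(gvec^2 / d)
    s2 <- sum_by_subj(gvec * r / d)
    sld <- sum_by_subj(log(d))
    srr <- sum_by_subj(r^2 / d)
    nj <- sum_by_subj(rep_len(1, length(y)))
    ll <- -0.5 * (nj * log(2 * pi) + sld + log1p(omega^2 * s1) +
                    srr - omega^2 * s2^2 / (1 + omega^2 * s1))
  }
  list(loglik = ll, eta_hat = eta, curvature = curv, engine = engine)
}

#' Per-subject marginal log-likelihood
#'
#' The contribution of each subject to the marginal log-likelihood,
#' integrating the log-normal clearance random effect out of the joint
#' density. The default `"agq"` engine uses adaptive Gauss-Hermite
#' quadrature centred at the conditional mode (exact up to quadrature
#' error, the reference); `"foce"` uses the first-order conditional
#' linearization with interaction.
#'
#' @param model a [vpa_model()].
#' @param data long-format dataset (see [prepare_dataset()]).
#' @param engine `"agq"` or `"foce"`.
#' @param nodes number of quadrature nodes for `"agq"`.
#' @return Named numeric vector, one log-likelihood per subject.
#' @export
subject_loglik <- function(model, data, engine = "agq", nodes = 21) {
  prep <- prepare_dataset(data)
  ll <- loglik_components(model, prep, engine = engine, nodes = nodes)$loglik
  stats::setNames(ll, prep$ids)
}

#' Objective function value (OFV)
#'
#' `-2` times the total marginal log-likelihood, the scale on which nested
#' models are compared (differences are asymptotically chi-squared).
#' Additive over subjects.
#'
#' @inheritParams subject_loglik
#' @return A single number.
#' @export
vpa_ofv <- function(model, data, engine = "agq", nodes = 21) {
  -2 * sum(subject_loglik(model, data, engine = engine, nodes = nodes))
}

#' Empirical Bayes estimates of the clearance random effect
#'
#' Conditional mode of each subject's `eta` given the data and the
#' population parameters. Subjects without quantified observations get the
#' prior mode, 0; as `omega_cl` approaches 0 all estimates shrink to 0.
#'
#' @inheritParams subject_loglik
#' @return Named numeric vector of modes, one per subject.
#' @export
empirical_bayes <- function(model, data) {
  prep <- prepare_dataset(data)
  comp <- loglik_components(model, prep, engine = "agq", nodes = 3)
  stats::setNames(comp$eta_hat, prep$ids)
}

# ---- parameter packing ------------------------------------------------------

# Names and transforms of the estimable parameters of a model. Scale
# parameters (clearance, volume, multipliers, omega, sigma) are estimated on
# the log scale to enforce positivity; continuous covariate coefficients are
# unconstrained.
param_specs <- function(model) {
  # generous physiological sanity bounds (natural scale); they keep the
  # optimizer off flat ridges (e.g. V/F drifting to infinity once the
  # trough approaches its infusion limit) without constraining any
  # plausible estimate
  specs <- list(
    list(name = "theta_cl", value = model$theta_cl, log = TRUE,
         lower = 1e-4, upper = 100),
    list(name = "theta_v", value = model$theta_v, log = TRUE,
         lower = 0.01, upper = 1000))
  for (ct in model$covariates) {
    if (ct$form == "multiplier") {
      for (lv in names(ct$coef)) {
        specs[[length(specs) + 1L]] <-
          list(name = paste0("mult_", ct$covariate, "_", lv),
               value = ct$coef[[lv]], log = TRUE, lower = 1e-3,
               upper = 1e3)
      }
    } else if (ct$form == "piecewise") {
      specs[[length(specs) + 1L]] <-
        list(name = paste0("beta_", ct$covariate, "_low"),
             value = ct$coef[["theta_low"]], log = FALSE, lower = -50,
             upper = 50)
      specs[[length(specs) + 1L]] <-
        list(name = paste0("beta_", ct$covariate, "_high"),
             value = ct$coef[["theta_high"]], log = FALSE, lower = -50,
             upper = 50)
    } else {
      specs[[length(specs) + 1L]] <-
        list(name = paste0("beta_", ct$covariate),
             value = ct$coef[[1L]], log = FALSE, lower = -50, upper = 50)
    }
  }
  if (model$omega_cl > 0) {
    specs[[length(specs) + 1L]] <-
      list(name = "omega_cl", value = model$omega_cl, log = TRUE,
           lower = 1e-4, upper = 5)
  }
  if (!is.null(model$error$sigma_add)) {
    specs[[length(specs) + 1L]] <-
      list(name = "sigma_add", value = model$error$sigma_add, log = TRUE,
           lower = 1e-3, upper = 1e3)
  }
  if (!is.null(model$error$sigma_prop)) {
    specs[[length(specs) + 1L]] <-
      list(name = "sigma_prop", value = model$error$sigma_prop, log = TRUE,
           lower = 1e-4, upper = 10)
  }
  specs
}

# Write a named vector of natural-scale parameter values back into a model.
model_set_params <- function(model, values) {
  nm <- names(values)
  take <- function(key) if (key %in% nm) values[[key]] else NULL
  if (!is.null(v <- take("theta_cl"))) model$theta_cl <- v
  if (!is.null(v <- take("theta_v"))) model$theta_v <- v
  if (!is.null(v <- take("omega_cl"))) model$omega_cl <- v
  if (!is.null(v <- take("sigma_add"))) model$error$sigma_add <- v
  if (!is.null(v <- take("sigma_prop"))) model$error$sigma_prop <- v
  for (i in seq_along(model$covariates)) {
    ct <- model$covariates[[i]]
    if (ct$form == "multiplier") {
      for (lv in names(ct$coef)) {
        if (!is.null(v <- take(paste0("mult_", ct$covariate, "_", lv)))) {
          model$covariates[[i]]$coef[[lv]] <- v
        }
      }
    } else if (ct$form == "piecewise") {
      if (!is.null(v <- take(paste0("beta_", ct$covariate, "_low")))) {
        model$covariates[[i]]$coef[["theta_low"]] <- v
      }
      if (!is.null(v <- take(paste0("beta_", ct$covariate, "_high")))) {
        model$covariates[[i]]$coef[["theta_high"]] <- v
      }
    } else {
      if (!is.null(v <- take(paste0("beta_", ct$covariate)))) {
        model$covariates[[i]]$coef[[1L]] <- v
      }
    }
  }
  model
}

# Extract current natural-scale values of all estimable parameters.
model_get_params <- function(model) {
  specs <- param_specs(model)
  stats::setNames(vapply(specs, `[[`, 0, "value"),
                  vapply(specs, `[[`, "", "name"))
}

pmap_build <- function(model, fixed = character()) {
  specs <- param_specs(model)
  nm <- vapply(specs, `[[`, "", "name")
  unknown <- setdiff(fixed, c(nm, "ka"))
  if (length(unknown)) stop("unknown parameter in 'fixed': ",
                            paste(unknown, collapse = ", "))
  est <- specs[!nm %in% fixed]
  if (length(est) == 0L) stop("no free parameters to estimate")
  enm <- vapply(est, `[[`, "", "name")
  elog <- vapply(est, `[[`, TRUE, "log")
  evalues <- vapply(est, `[[`, 0, "value")
  elo <- vapply(est, `[[`, 0, "lower")
  eup <- vapply(est, `[[`, 0, "upper")
  to_trans <- function(v) {
    v[elog] <- log(v[elog])
    v
  }
  from_trans <- function(p) {
    p[elog] <- exp(p[elog])
    p
  }
  list(
    names = enm,
    is_log = elog,
    init = to_trans(evalues),
    lower = to_trans(elo),
    upper = to_trans(eup),
    to_natural = function(p) stats::setNames(from_trans(p), enm),
    unpack = function(p) {
      model_set_params(model, stats::setNames(from_trans(p), enm))
    }
  )
}

# ---- fitting ----------------------------------------------------------------

#' Fit a population-PK model by maximum marginal likelihood
#'
#' Minimizes the OFV over all non-fixed parameters with `ka` always fixed.
#' Scale parameters are log-transformed internally so positivity is
#' automatic. Standard errors come from the finite-difference Hessian of
#' half the OFV with respect to the natural-scale parameters; a singular or
#' non-positive-definite Hessian yields missing RSEs rather than an error.
#' Non-convergence is flagged on the result (bootstrap replicates need to
#' count failures), not raised.
#'
#' @param model a [vpa_model()] whose current parameter values serve as
#'   initial estimates.
#' @param data long-format dataset.
#' @param fixed character vector of parameter names to hold at their
#'   initial values (see [coef.vpa_fit()] for the naming scheme).
#' @param engine likelihood engine, `"agq"` (reference) or `"foce"`.
#' @param nodes quadrature nodes for `"agq"`.
#' @param compute_se compute the Hessian-based RSEs (skipped for speed in
#'   stepwise search and bootstrap replicates).
#' @param control passed to [stats::nlminb()]; defaults
#'   `iter.max = 500`, `eval.max = 4000`, `rel.tol = 1e-10`.
#' @return An object of class `vpa_fit` with elements `model` (updated
#'   spec), `estimates`, `se`, `rse_pct`, `ofv`, `aic`, `bic`, `n_params`,
#'   `ebes`, `eta_shrinkage_pct`, `eps_shrinkage_pct`, `converged`,
#'   `n_subjects`, `n_obs`.
#' @export
vpa_fit <- function(model, data, fixed = character(), engine = "agq",
                    nodes = 21, compute_se = TRUE, control = list()) {
  prep <- prepare_dataset(data)
  pm <- pmap_build(model, fixed)
  obj <- function(p) {
    m <- pm$unpack(p)
    val <- tryCatch(-2 * sum(loglik_components(m, prep, engine = engine,
                                               nodes = nodes)$loglik),
                    error = function(e) NA_real_)
    if (!is.finite(val)) 1e10 else val
  }
  ctrl <- utils::modifyList(list(iter.max = 500, eval.max = 4000,
                                 rel.tol = 1e-10), control)
  opt <- stats::nlminb(pm$init, obj, control = ctrl, lower = pm$lower,
                       upper = pm$upper)
  converged <- opt$convergence == 0
  if (!converged) {
    # nlminb reports "false convergence" when started at (or stepping
    # straight to) a flat optimum; accept the solution if the numerical
    # gradient vanishes there.
    h <- 1e-5
    grad <- vapply(seq_along(opt$par), function(i) {
      e <- replace(numeric(length(opt$par)), i, h)
      (obj(opt$par + e) - obj(opt$par - e)) / (2 * h)
    }, 0)
    converged <- max(abs(grad)) < 1e-2
  }
  est <- pm$to_natural(opt$par)
  m_hat <- pm$unpack(opt$par)
  comp <- loglik_components(m_hat, prep, engine = engine, nodes = nodes)
  ofv <- -2 * sum(comp$loglik)
  p <- length(est)

  se <- rse <- stats::setNames(rep(NA_real_, p), names(est))
  if (compute_se) {
    half_ofv_nat <- function(th) {
      m <- model_set_params(m_hat, stats::setNames(th, names(est)))
      val <- tryCatch(-sum(loglik_components(m, prep, engine = engine,
                                             nodes = nodes)$loglik),
                      error = function(e) NA_real_)
      if (!is.finite(val)) 1e10 else val
    }
    hess <- tryCatch(pracma::hessian(half_ofv_nat, unname(est)),
                     error = function(e) NULL)
    if (!is.null(hess)) {
      cov <- tryCatch(solve(hess), error = function(e) NULL)
      if (!is.null(cov) && all(is.finite(diag(cov))) &&
          all(diag(cov) > 0)) {
        se <- stats::setNames(sqrt(diag(cov)), names(est))
        rse <- 100 * se / abs(est)
      }
    }
  }

  ebes <- stats::setNames(comp$eta_hat, prep$ids)
  shr <- shrinkage_from(m_hat, prep, comp)
  structure(list(
    model = m_hat,
    estimates = est,
    fixed = fixed,
    se = se,
    rse_pct = rse,
    ofv = ofv,
    n_params = p,
    aic = ofv + 2 * p,
    bic = ofv + p * log(prep$n_obs),
    ebes = ebes,
    eta_shrinkage_pct = shr[["eta"]],
    eps_shrinkage_pct = shr[["eps"]],
    converged = converged,
    message = opt$message,
    iterations = opt$iterations,
    engine = engine,
    nodes = nodes,
    n_subjects = prep$n_subj,
    n_obs = prep$n_obs,
    data = data
  ), class = "vpa_fit")
}

# eta- and epsilon-shrinkage from fitted components.
shrinkage_from <- function(model, prep, comp) {
  eta_shr <- NA_real_
  if (model$omega_cl > 0 && prep$n_subj >= 2L) {
    eta_shr <- 100 * (1 - stats::sd(comp$eta_hat) / model$omega_cl)
  }
  cl_typ <- cl_typ_rows(model, prep)
  ipred <- conc_ss_(prep$dose, prep$tau, prep$tt,
                    cl_typ * exp(comp$eta_hat[prep$idx]),
                    model$theta_v, model$ka)
  iwres <- (prep$y - ipred) / resid_sd(model$error, ipred)
  eps_shr <- if (length(iwres) >= 2L) 100 * (1 - stats::sd(iwres))
             else NA_real_
  c(eta = eta_shr, eps = eps_shr)
}

#' Shrinkage of empirical Bayes estimates and residuals
#'
#' Eta-shrinkage `100 * (1 - SD(eta_hat) / omega)` quantifies how strongly
#' sparse data pull individual estimates toward the population mean;
#' epsilon-shrinkage `100 * (1 - SD(IWRES))` does the same for the
#' individual weighted residuals. Undefined (NA) when `omega_cl = 0`.
#'
#' @param fit a [vpa_fit()] result.
#' @return Named vector `c(eta = , eps = )`, in percent.
#' @export
vpa_shrinkage <- function(fit) {
  stopifnot(inherits(fit, "vpa_fit"))
  c(eta = fit$eta_shrinkage_pct, eps = fit$eps_shrinkage_pct)
}

#' @export
coef.vpa_fit <- function(object, ...) object$estimates

#' @export
logLik.vpa_fit <- function(object, ...) {
  structure(-object$ofv / 2, df = object$n_params, class = "logLik")
}

#' @export
print.vpa_fit <- function(x, ...) {
  cat(sprintf("Population-PK fit (%s engine): %d subjects, %d observations\n",
              x$engine, x$n_subjects, x$n_obs))
  cat(sprintf("  OFV %.3f | AIC %.3f | BIC %.3f | %s\n",
              x$ofv, x$aic, x$bic,
              if (x$converged) "converged" else "NOT converged"))
  tab <- data.frame(estimate = signif(x$estimates, 4),
                    rse_pct = signif(x$rse_pct, 3))
  print(tab)
  cat(sprintf("  eta-shrinkage %.1f%% | eps-shrinkage %.1f%%\n",
              x$eta_shrinkage_pct, x$eps_shrinkage_pct))
  invisible(x)
}

# ---- residual diagnostics ---------------------------------------------------

#' Goodness-of-fit records with conditional weighted residuals
#'
#' One record per quantified observation: observed value (DV), population
#' prediction (PRED, `eta = 0`), individual prediction (IPRED, at the
#' empirical Bayes mode) and the conditional weighted residual (CWRES).
#' CWRES decorrelates each subject's residual vector with the inverse
#' square root of the FOCE-linearized marginal covariance
#' `V = G omega^2 G' + diag(sd^2)` evaluated at the conditional mode; under
#' the true model CWRES are approximately standard normal.
#'
#' @param model a fitted [vpa_model()] (or take it from a [vpa_fit()]).
#' @param data long-format dataset.
#' @return Data frame `ID`, `TIME`, `DV`, `PRED`, `IPRED`, `CWRES`.
#' @export
cwres_table <- function(model, data) {
  prep <- prepare_dataset(data)
  comp <- loglik_components(model, prep, engine = "agq", nodes = 3)
  eta <- comp$eta_hat
  cl_typ <- cl_typ_rows(model, prep)
  fconc <- function(e) conc_ss_(prep$dose, prep$tau, prep$tt,
                                cl_typ * exp(e[prep$idx]),
                                model$theta_v, model$ka)
  pred <- fconc(numeric(prep$n_subj))
  ipred <- fconc(eta)
  dh <- 1e-4
  gvec <- (fconc(eta + dh) - fconc(eta - dh)) / (2 * dh)
  sd_i <- resid_sd(model$error, ipred)
  omega <- model$omega_cl
  resid <- prep$y - (ipred - gvec * eta[prep$idx])
  cwres <- numeric(length(resid))
  for (j in prep$present) {
    rows <- which(prep$idx == j)
    g <- gvec[rows]
    vmat <- omega^2 * tcrossprod(g) + diag(sd_i[rows]^2,
                                           nrow = length(rows))
    ev <- eigen(vmat, symmetric = TRUE)
    if (any(ev$values <= 0)) {
      stop("singular marginal covariance for subject ", prep$ids[j])
    }
    vinv_sqrt <- ev$vectors %*% (t(ev$vectors) / sqrt(ev$values))
    cwres[rows] <- as.vector(vinv_sqrt %*% resid[rows])
  }
  data.frame(ID = prep$data$ID[prep$ok],
             TIME = prep$tt,
             DV = prep$y,
             PRED = pred,
             IPRED = ipred,
             CWRES = cwres)
}
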