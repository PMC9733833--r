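# Model evaluation: nonparametric bootstrap, visual predictive check,
# goodness-of-fit summaries.

#' Subject-level nonparametric bootstrap of a fitted model
#'
#' Resamples subjects (not observations, preserving within-subject
#' correlation) with replacement to the original subject count, refits each
#' replicate starting from the reference estimates, and summarizes the
#' successful replicates by their median and 2.5th/97.5th percentile per
#' parameter. A replicate counts as successful when the optimizer reports
#' convergence with a finite OFV and, when `hessian_check` is on, the
#' numerical Hessian at its optimum is positive definite.
#'
#' @param fit reference [vpa_fit()].
#' @param n_runs number of bootstrap replicates (1000 for a full analysis;
#'   100-200 give usable intervals at a fraction of the cost).
#' @param seed RNG seed governing all resampling.
#' @param hessian_check require a positive-definite Hessian for success.
#' @return Object of class `vpa_bootstrap`: `n_runs`, `n_success`,
#'   `success_rate_pct`, `reference`, `median`, `ci_lower`, `ci_upper`,
#'   `relative_error_pct` (`100 * (median - reference) / reference`) and
#'   the matrix of replicate estimates.
#' @export
vpa_bootstrap <- function(fit, n_runs = 1000, seed = 1,
                          hessian_check = TRUE) {
  stopifnot(inherits(fit, "vpa_fit"), n_runs >= 1)
  set.seed(seed)
  data <- fit$data
  ids <- unique(data$ID)
  rows_by_id <- split(seq_len(nrow(data)), match(data$ID, ids))
  est <- matrix(NA_real_, n_runs, length(fit$estimates),
                dimnames = list(NULL, names(fit$estimates)))
  ok <- logical(n_runs)
  for (r in seq_len(n_runs)) {
    sel <- sample(length(ids), replace = TRUE)
    rows <- rows_by_id[sel]
    nd <- data[unlist(rows), , drop = FALSE]
    nd$ID <- rep(seq_along(sel), lengths(rows))
    f2 <- tryCatch(
      vpa_fit(fit$model, nd, fixed = fit$fixed, engine = fit$engine,
              nodes = fit$nodes, compute_se = FALSE),
      error = function(e) NULL)
    good <- !is.null(f2) && f2$converged && is.finite(f2$ofv)
    if (good && hessian_check) {
      good <- is_pd_at_optimum(f2)
    }
    if (good) {
      ok[r] <- TRUE
      est[r, ] <- f2$estimates
    }
  }
  if (!any(ok)) stop("all bootstrap replicates failed to converge")
  em <- est[ok, , drop = FALSE]
  med <- apply(em, 2, stats::median)
  structure(list(
    n_runs = n_runs,
    n_success = sum(ok),
    success_rate_pct = 100 * sum(ok) / n_runs,
    reference = fit$estimates,
    median = med,
    ci_lower = apply(em, 2, stats::quantile, 0.025),
    ci_upper = apply(em, 2, stats::quantile, 0.975),
    relative_error_pct = 100 * (med - fit$estimates) / fit$estimates,
    estimates = em
  ), class = "vpa_bootstrap")
}

# Positive-definiteness of the OFV Hessian on the transformed (log) scale,
# the cheap convergence diagnostic used for bootstrap replicates.
is_pd_at_optimum <- function(fit) {
  prep <- prepare_dataset(fit$data)
  pm <- pmap_build(fit$model, fit$fixed)
  obj <- function(p) {
    m <- pm$unpack(p)
    val <- tryCatch(-2 * sum(loglik_components(m, prep,
                                               engine = fit$engine,
                                               nodes = fit$nodes)$loglik),
                    error = function(e) NA_real_)
    if (!is.finite(val)) 1e10 else val
  }
  h <- tryCatch(stats::optimHess(pm$init, obj), error = function(e) NULL)
  !is.null(h) && all(eigen(h, symmetric = TRUE,
                           only.values = TRUE)$values > 0)
}

#' @export
print.vpa_bootstrap <- function(x, ...) {
  cat(sprintf("Bootstrap: %d/%d successful (%.1f%%)\n", x$n_success,
              x$n_runs, x$success_rate_pct))
  print(data.frame(reference = signif(x$reference, 4),
                   median = signif(x$median, 4),
                   ci_2.5 = signif(x$ci_lower, 4),
                   ci_97.5 = signif(x$ci_upper, 4),
                   rel_error_pct = round(x$relative_error_pct, 1)))
  invisible(x)
}

#' Bootstrap relative error
#'
#' `100 * (bootstrap median - reference estimate) / reference estimate`,
#' the accuracy summary reported alongside bootstrap medians.
#'
#' @param median bootstrap median (scalar or vector).
#' @param reference reference (final-model) estimate.
#' @return Relative error in percent.
#' @export
bootstrap_relative_error <- function(median, reference) {
  100 * (median - reference) / reference
}

# Merge adjacent bins until each holds at least min_n observations.
merge_small_bins <- function(breaks, v, min_n = 5) {
  repeat {
    counts <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE,
                                    all.inside = TRUE),
                       nbins = length(breaks) - 1L)
    if (all(counts >= min_n) || length(breaks) <= 2L) break
    i <- which.min(counts)
    drop <- if (i == 1L) 2L
            else if (i == length(counts)) length(breaks) - 1L
            else if (counts[i - 1L] <= counts[i + 1L]) i else i + 1L
    message("merging sparse bin (", counts[i], " observations)")
    breaks <- breaks[-drop]
  }
  breaks
}

#' Visual predictive check
#'
#' Simulates the original design (same subjects, regimens and sampling
#' times) `n_sim` times from the model with fresh random effects and
#' residual noise, and compares the observed 5th/50th/95th percentiles per
#' bin with the simulation-based confidence band of the same percentiles.
#' All troughs are drawn at the pre-dose time, so the time axis is narrow;
#' binning by age is offered as the informative alternative.
#'
#' @param fit a [vpa_fit()] (or any list with `model` and `data`).
#' @param n_sim number of simulated datasets (1000 for a full VPC).
#' @param seed RNG seed.
#' @param binning `"age"` (default: subject age, the model's main
#'   covariate axis) or `"time"` (time after dose).
#' @param n_bins target number of quantile bins; bins with fewer than 5
#'   observations are merged.
#' @param probs percentiles of interest.
#' @param ci level of the simulated confidence band.
#' @return Object of class `vpa_vpc`: a data frame with one row per
#'   bin-percentile (`bin`, `bin_low`, `bin_high`, `n_obs`, `prob`,
#'   `observed`, `band_low`, `band_median`, `band_high`) plus attributes
#'   `coverage` (fraction of observed percentiles inside their band) and
#'   `mean_band_width`.
#' @export
vpa_vpc <- function(fit, n_sim = 1000, seed = 1,
                    binning = c("age", "time"), n_bins = 6,
                    probs = c(0.05, 0.5, 0.95), ci = 0.95) {
  binning <- match.arg(binning)
  stopifnot(n_sim >= 1)
  model <- fit$model
  prep <- prepare_dataset(fit$data)
  set.seed(seed)
  v <- switch(binning,
              age = fit$data$AGE[prep$ok],
              time = prep$tt)
  qs <- unique(stats::quantile(v, seq(0, 1, length.out = n_bins + 1L)))
  if (length(qs) < 2L) qs <- c(qs, qs + 1e-9)
  breaks <- merge_small_bins(qs, v)
  bin_of <- findInterval(v, breaks, rightmost.closed = TRUE,
                         all.inside = TRUE)
  nb <- length(breaks) - 1L

  perc_by_bin <- function(y) {
    out <- matrix(NA_real_, nb, length(probs))
    for (b in seq_len(nb)) {
      out[b, ] <- stats::quantile(y[bin_of == b], probs, names = FALSE)
    }
    out
  }
  obs_p <- perc_by_bin(prep$y)

  cl_typ <- cl_typ_rows(model, prep)
  sim_p <- array(NA_real_, c(n_sim, nb, length(probs)))
  for (s in seq_len(n_sim)) {
    eta <- stats::rnorm(prep$n_subj, 0, model$omega_cl)
    f <- conc_ss_(prep$dose, prep$tau, prep$tt,
                  cl_typ * exp(eta[prep$idx]), model$theta_v, model$ka)
    y <- f + stats::rnorm(length(f)) * resid_sd(model$error, f)
    sim_p[s, , ] <- perc_by_bin(y)
  }
  a <- (1 - ci) / 2
  res <- do.call(rbind, lapply(seq_len(nb), function(b) {
    data.frame(
      bin = b,
      bin_low = breaks[b],
      bin_high = breaks[b + 1L],
      n_obs = sum(bin_of == b),
      prob = probs,
      observed = obs_p[b, ],
      band_low = apply(sim_p[, b, , drop = FALSE], 3, stats::quantile, a),
      band_median = apply(sim_p[, b, , drop = FALSE], 3, stats::median),
      band_high = apply(sim_p[, b, , drop = FALSE], 3, stats::quantile,
                        1 - a))
  }))
  stopifnot(all(res$band_low <= res$band_median + 1e-12),
            all(res$band_median <= res$band_high + 1e-12))
  attr(res, "coverage") <- mean(res$observed >= res$band_low &
                                  res$observed <= res$band_high)
  attr(res, "mean_band_width") <- mean(res$band_high - res$band_low)
  class(res) <- c("vpa_vpc", class(res))
  res
}

#' Goodness-of-fit table and trend summaries
#'
#' Per-observation records (DV, PRED, IPRED, CWRES; see [cwres_table()])
#' together with the least-squares slope and intercept of DV against PRED
#' and IPRED, and the trend slopes of CWRES against PRED and against time
#' after dose (with standard errors). A well-specified model has DV~IPRED
#' slope near 1 and CWRES trend slopes near 0.
#'
#' @param fit a [vpa_fit()].
#' @return Object of class `vpa_gof`: list with `records` and `slopes`.
#' @export
gof_table <- function(fit) {
  rec <- cwres_table(fit$model, fit$data)
  lm_sum <- function(formula) {
    cf <- summary(stats::lm(formula, data = rec))$coefficients
    list(intercept = cf[1, 1], slope = cf[2, 1], slope_se = cf[2, 2])
  }
  slopes <- list(dv_pred = lm_sum(DV ~ PRED),
                 dv_ipred = lm_sum(DV ~ IPRED),
                 cwres_pred = lm_sum(CWRES ~ PRED),
                 cwres_time = if (stats::var(rec$TIME) > 0) {
                   lm_sum(CWRES ~ TIME)
                 } else NULL)
  structure(list(records = rec, slopes = slopes), class = "vpa_gof")
}

#' @export
print.vpa_gof <- function(x, ...) {
  cat(sprintf("GOF: %d observations\n", nrow(x$records)))
  for (nm in names(x$slopes)) {
    s <- x$slopes[[nm]]
    if (is.null(s)) next
    cat(sprintf("  %-10s slope %.3f (se %.3f), intercept %.3f\n", nm,
                s$slope, s$slope_se, s$intercept))
  }
  invisible(x)
}
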