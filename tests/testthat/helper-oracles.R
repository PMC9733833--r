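# Shared fixtures and independent oracles used across test files.

# Single-dose concentration after one oral dose (no accumulation); the
# steady-state closed form must agree with a long superposition of these.
single_dose_conc <- function(dose, t, cl, v, ka) {
  ke <- cl / v
  dose * ka / (v * (ka - ke)) * (exp(-ke * t) - exp(-ka * t))
}

superposition_trough <- function(dose, tau, t, cl, v, ka, n_doses = 400) {
  sum(single_dose_conc(dose, t + (seq_len(n_doses) - 1) * tau, cl, v, ka))
}

# Brute-force marginal log-likelihood for one subject: dense trapezoid
# integration of the joint density over eta, independent of the quadrature
# path it checks.
brute_marginal_loglik <- function(model, subj_data, npts = 1e5,
                                  width = 6) {
  omega <- model$omega_cl
  etas <- seq(-width * omega, width * omega, length.out = npts)
  cl0 <- typical_clearance(model, subj_data)
  lg <- dnorm(etas, 0, omega, log = TRUE)
  for (j in seq_len(nrow(subj_data))) {
    f <- steady_state_conc(subj_data$DOSE_MG[j], subj_data$II_H[j],
                           subj_data$TIME_H[j], cl0[j] * exp(etas),
                           model$theta_v, model$ka)
    sd <- if (model$error$kind == "additive") model$error$sigma_add else
      stop("oracle supports additive error only")
    lg <- lg + dnorm(subj_data$DV[j], f, sd, log = TRUE)
  }
  m <- max(lg)
  m + log(pracma::trapz(etas, exp(lg - m)))
}

# Dense grid maximizer of the conditional density of eta (EBE oracle).
grid_ebe <- function(model, subj_data, width = 6, npts = 80001) {
  omega <- model$omega_cl
  etas <- seq(-width * omega, width * omega, length.out = npts)
  cl0 <- typical_clearance(model, subj_data)
  lg <- dnorm(etas, 0, omega, log = TRUE)
  for (j in seq_len(nrow(subj_data))) {
    f <- steady_state_conc(subj_data$DOSE_MG[j], subj_data$II_H[j],
                           subj_data$TIME_H[j], cl0[j] * exp(etas),
                           model$theta_v, model$ka)
    lg <- lg + dnorm(subj_data$DV[j], f, model$error$sigma_add,
                     log = TRUE)
  }
  etas[which.max(lg)]
}

# Session-level cache of the default synthetic cohort and its final-model
# refit, shared by several test files to keep the suite fast.
.test_cache <- new.env(parent = emptyenv())

default_cohort <- function() {
  if (is.null(.test_cache$cohort)) {
    .test_cache$cohort <- generate_cohort(cohort_config(), seed = 20260901)
  }
  .test_cache$cohort
}

default_fit <- function() {
  if (is.null(.test_cache$fit)) {
    .test_cache$fit <- vpa_fit(vpa_final_model(), default_cohort(),
                               compute_se = FALSE)
  }
  .test_cache$fit
}

# Neutral starting values for refitting the final-model structure.
recovery_init_model <- function() {
  vpa_model(theta_cl = 0.15, theta_v = 3, ka = 1.9,
            covariates = list(
              cov_power("AGE", theta = 0.2, ref = 5),
              cov_multiplier("rs3789243", ref_level = "AA",
                             multipliers = c(AG = 1, GG = 1))),
            omega_cl = 0.25,
            error = vpa_error("additive", sigma_add = 10))
}
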