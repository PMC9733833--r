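# The estimation engine: marginal likelihood, fitting, empirical Bayes
# estimates, shrinkage and residual diagnostics.

noise_free_dataset <- function(model, n = 8, seed = 5) {
  cfg <- cohort_config(n_subjects = n, model = model)
  d <- generate_cohort(cfg, seed = seed)
  d$DV <- predict_trough(model, d, eta = 0)
  d
}

test_that("degenerate likelihood (omega = 0) matches Gaussian closed forms", {
  m <- vpa_model(theta_cl = 0.214, theta_v = 3.63, omega_cl = 0,
                 covariates = list(cov_power("AGE", 0.357, 5)),
                 error = vpa_error("additive", sigma_add = 1))
  d <- data.frame(ID = 1, AGE = 5, WT = 20, SEX = 0, DOSE_MG = 250,
                  II_H = 12, TIME_H = 12, DV = NA)
  d$DV <- predict_trough(m, d, eta = 0)  # zero residual
  # single observation at its mode: log density of N(0, 1)
  expect_equal(unname(subject_loglik(m, d)), -0.5 * log(2 * pi),
               tolerance = 1e-12)
  # doubling sigma with zero residuals shifts the log-lik by -n log 2
  d3 <- rbind(d, d, d)
  d3$ID <- 1:3
  m2 <- m
  m2$error$sigma_add <- 2
  expect_equal(sum(subject_loglik(m2, d3)) - sum(subject_loglik(m, d3)),
               -3 * log(2), tolerance = 1e-10)
  # OFV closed form with nonzero residuals
  d3$DV <- d3$DV + c(1, -2, 0.5)
  sig <- 1.3
  m3 <- m
  m3$error$sigma_add <- sig
  expect_equal(vpa_ofv(m3, d3),
               sum(log(2 * pi * sig^2) + c(1, -2, 0.5)^2 / sig^2),
               tolerance = 1e-10)
})

test_that("adaptive quadrature matches dense brute-force integration", {
  m <- vpa_final_model()
  d <- generate_cohort(cohort_config(n_subjects = 5), seed = 11)
  ll <- subject_loglik(m, d, nodes = 41)
  for (id in unique(d$ID)) {
    oracle <- brute_marginal_loglik(m, d[d$ID == id, ], npts = 1e5)
    expect_equal(unname(ll[as.character(id)]), oracle,
                 tolerance = 1e-6)
  }
})

test_that("OFV is additive over subjects", {
  m <- vpa_final_model()
  d <- generate_cohort(cohort_config(n_subjects = 12), seed = 3)
  ids <- unique(d$ID)
  half1 <- d[d$ID %in% ids[1:6], ]
  half2 <- d[d$ID %in% ids[7:12], ]
  expect_equal(vpa_ofv(m, d), vpa_ofv(m, half1) + vpa_ofv(m, half2),
               tolerance = 1e-9)
  one <- d[d$ID == ids[1], ]
  expect_equal(vpa_ofv(m, one), -2 * sum(subject_loglik(m, one)))
})

test_that("noise-free data are recovered exactly and AIC/BIC identities hold", {
  gen <- vpa_model(theta_cl = 0.214, theta_v = 3.63, omega_cl = 0,
                   covariates = list(cov_power("AGE", 0.357, 5)),
                   error = vpa_error("additive", sigma_add = 1e-4))
  d <- noise_free_dataset(gen, n = 10, seed = 5)
  init <- gen
  init$theta_cl <- 0.25
  init$theta_v <- 3
  init$covariates[[1]]$coef[["theta"]] <- 0.2
  f <- vpa_fit(init, d, fixed = "sigma_add", compute_se = FALSE)
  expect_true(f$converged)
  expect_equal(f$estimates[["theta_cl"]], 0.214, tolerance = 1e-3)
  expect_equal(f$estimates[["theta_v"]], 3.63, tolerance = 1e-3)
  expect_equal(f$estimates[["beta_AGE"]], 0.357, tolerance = 1e-3)
  expect_identical(f$aic, f$ofv + 2 * f$n_params)
  expect_identical(f$bic, f$ofv + f$n_params * log(f$n_obs))
})

test_that("distinct starting values reach the same optimum", {
  d <- generate_cohort(cohort_config(n_subjects = 40), seed = 9)
  inits <- list(c(0.15, 3.0, 0.2, 0.25, 10),
                c(0.30, 5.0, 0.5, 0.10, 15),
                c(0.10, 2.0, 0.1, 0.35, 8))
  ofvs <- vapply(inits, function(p) {
    m <- vpa_model(theta_cl = p[1], theta_v = p[2],
                   covariates = list(cov_power("AGE", p[3], 5)),
                   omega_cl = p[4],
                   error = vpa_error("additive", sigma_add = p[5]))
    vpa_fit(m, d, compute_se = FALSE)$ofv
  }, 0)
  expect_lt(max(ofvs) - min(ofvs), 0.1)
})

test_that("empirical Bayes estimates match a dense grid search", {
  m <- vpa_final_model()
  d <- generate_cohort(cohort_config(n_subjects = 6), seed = 21)
  eb <- empirical_bayes(m, d)
  for (id in unique(d$ID)[1:4]) {
    expect_lt(abs(unname(eb[as.character(id)]) -
                    grid_ebe(m, d[d$ID == id, ])), 1e-4)
  }
  # degenerate prior pins the estimates at zero
  m_small <- m
  m_small$omega_cl <- 1e-6
  expect_true(all(abs(empirical_bayes(m_small, d)) < 1e-5))
  # a subject with no quantified observations sits at the prior mode
  d2 <- d
  d2$DV[d2$ID == d2$ID[1]] <- NA
  eb2 <- empirical_bayes(m, d2)
  expect_identical(unname(eb2[as.character(d$ID[1])]), 0)
  expect_equal(eb2[-1], eb[-1], tolerance = 1e-8)
})

test_that("shrinkage summaries behave as defined", {
  # rich data (20 troughs per subject) shrink very little
  cfg <- cohort_config(n_subjects = 25, obs_probs = c("20" = 1))
  d <- generate_cohort(cfg, seed = 31)
  f <- vpa_fit(vpa_final_model(), d, compute_se = FALSE)
  expect_lt(f$eta_shrinkage_pct, 15)
  # the reported value is exactly the SD formula on the reported EBEs
  expect_equal(f$eta_shrinkage_pct,
               100 * (1 - sd(f$ebes) / f$estimates[["omega_cl"]]),
               tolerance = 1e-8)
  expect_identical(vpa_shrinkage(f),
                   c(eta = f$eta_shrinkage_pct,
                     eps = f$eps_shrinkage_pct))
  expect_lte(f$eta_shrinkage_pct, 100)
})

test_that("CWRES reduce to weighted residuals without a random effect and are standard normal under the true model", {
  m0 <- vpa_model(theta_cl = 0.214, theta_v = 3.63, omega_cl = 0,
                  covariates = list(cov_power("AGE", 0.357, 5)),
                  error = vpa_error("additive", sigma_add = 5))
  d0 <- noise_free_dataset(m0, n = 6, seed = 41)
  set.seed(1)
  d0$DV <- d0$DV + rnorm(nrow(d0), 0, 5)
  rec0 <- cwres_table(m0, d0)
  expect_equal(rec0$CWRES, (rec0$DV - rec0$PRED) / 5, tolerance = 1e-9)
  # full cohort simulated from the model itself
  rec <- cwres_table(vpa_final_model(), default_cohort())
  expect_gte(nrow(rec), 300)
  expect_gt(mean(rec$CWRES), -0.15)
  expect_lt(mean(rec$CWRES), 0.15)
  expect_gt(sd(rec$CWRES), 0.85)
  expect_lt(sd(rec$CWRES), 1.15)
  expect_gte(mean(abs(rec$CWRES) <= 2), 0.93)
})

test_that("quadrature and FOCE-I engines agree on well-behaved data", {
  m <- vpa_final_model()
  d <- default_cohort()
  expect_lt(abs(vpa_ofv(m, d, engine = "agq") -
                  vpa_ofv(m, d, engine = "foce")), 1)
})
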