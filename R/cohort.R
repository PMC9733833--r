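# Synthetic study-cohort generator. Emulates the demographic, dosing and
# genotype structure of the pediatric valproic acid TDM population (103
# children, 376 steady-state troughs) so that estimation, selection and
# evaluation can be exercised without patient-level data.

# Moments of a log-normal truncated to [a, b].
trunc_lnorm_moments <- function(meanlog, sdlog, a, b) {
  za <- (log(a) - meanlog) / sdlog
  zb <- (log(b) - meanlog) / sdlog
  mass <- stats::pnorm(zb) - stats::pnorm(za)
  mk <- function(k) {
    exp(k * meanlog + k^2 * sdlog^2 / 2) *
      (stats::pnorm(zb - k * sdlog) - stats::pnorm(za - k * sdlog)) / mass
  }
  m1 <- mk(1)
  m2 <- mk(2)
  c(mean = m1, sd = sqrt(max(m2 - m1^2, 0)))
}

# Solve (meanlog, sdlog) so the truncated distribution matches a target
# mean and SD.
solve_trunc_lnorm <- function(mean, sd, a, b) {
  start <- c(log(mean) - 0.5 * log(1 + (sd / mean)^2),
             sqrt(log(1 + (sd / mean)^2)))
  fn <- function(p) {
    m <- trunc_lnorm_moments(p[1], exp(p[2]), a, b)
    (m[["mean"]] - mean)^2 + (m[["sd"]] - sd)^2
  }
  opt <- stats::optim(c(start[1], log(start[2])), fn)
  c(meanlog = opt$par[1], sdlog = exp(opt$par[2]))
}

rtrunc_lnorm <- function(n, meanlog, sdlog, a, b) {
  u <- stats::runif(n, stats::plnorm(a, meanlog, sdlog),
                    stats::plnorm(b, meanlog, sdlog))
  stats::qlnorm(u, meanlog, sdlog)
}

rtrunc_norm <- function(n, mean, sd, a, b) {
  u <- stats::runif(n, stats::pnorm(a, mean, sd), stats::pnorm(b, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Pediatric weight-for-age model
#'
#' The standard pediatric approximation `weight = 2 * (age + 4)` kg,
#' optionally clamped. Used deterministically in dose simulation and, with
#' multiplicative log-normal noise, in the cohort generator.
#'
#' @param age_y age in years.
#' @param clamp two-element range the weight is clipped to.
#' @return Weight in kg.
#' @export
weight_for_age <- function(age_y, clamp = c(10, 40)) {
  pmin(pmax(2 * (age_y + 4), clamp[1]), clamp[2])
}

#' Inverse of [weight_for_age()]: `age = weight/2 - 4`, clamped to the
#' pediatric range.
#' @param weight_kg weight in kg.
#' @param clamp age range in years.
#' @return Age in years.
#' @export
age_for_weight <- function(weight_kg, clamp = c(0.5, 15)) {
  pmin(pmax(weight_kg / 2 - 4, clamp[1]), clamp[2])
}

#' Configuration of the synthetic cohort generator
#'
#' Defaults reproduce the study conditions: 103 subjects with 2-5 troughs
#' each (mean about 3.65, i.e. roughly 376 in total); ages from a truncated
#' log-normal matched to mean 5.30 y, SD 3.39 y on \[0.5, 15\] (right-skewed,
#' as the minimum of 0.5 y forces); weights from the pediatric
#' weight-for-age rule with multiplicative log-normal noise, clipped to
#' \[6.5, 52\] kg; daily doses from a truncated normal with mean 23.8 and SD
#' 5.7 mg/kg/day on \[9.9, 45.7\]; genotypes drawn under Hardy-Weinberg
#' proportions at the panel's observed allele frequencies; co-medication
#' flags as independent Bernoulli draws at the observed sample proportions;
#' and troughs generated from the final published model (additive residual,
#' 1 mg/L quantification limit handled by resampling).
#'
#' @param n_subjects number of virtual children.
#' @param obs_probs named probabilities over observations per subject.
#' @param age_mean,age_sd,age_range target moments and support of the age
#'   distribution (years).
#' @param weight_cv log-scale SD of the multiplicative weight noise.
#' @param weight_range admissible weight range (kg).
#' @param dose_mean,dose_sd,dose_range daily-dose distribution (mg/kg/day).
#' @param dose_round granularity of the practical per-administration dose
#'   (mg).
#' @param snp_counts genotype-count table as from [vpa_snp_counts()];
#'   allele frequencies are derived from it.
#' @param comed_probs named per-drug probabilities.
#' @param model generating [vpa_model()].
#' @param tau dosing interval of a twice-daily regimen (h).
#' @param tid_prob fraction of subjects on a three-times-daily (q8h)
#'   regimen rather than twice daily; the cohort's children took the drug
#'   two to three times a day, and the mix of intervals is also what makes
#'   the apparent volume identifiable from trough-only data.
#' @param lloq lower limit of quantification (mg/L); simulated
#'   concentrations below it are redrawn (and counted).
#' @param time_jitter SD (h) of optional jitter on the nominal trough
#'   sampling time, 0 for strict troughs.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 103,
                          obs_probs = c("2" = 0.15, "3" = 0.25,
                                        "4" = 0.40, "5" = 0.20),
                          age_mean = 5.30, age_sd = 3.39,
                          age_range = c(0.5, 15),
                          weight_cv = 0.15, weight_range = c(6.5, 52),
                          dose_mean = 23.8, dose_sd = 5.7,
                          dose_range = c(9.9, 45.7),
                          dose_round = 5,
                          snp_counts = vpa_snp_counts(),
                          comed_probs = c(LEV = 0.1383, OXC = 0.1117,
                                          TPM = 0.0426, CNZ = 0.0372,
                                          PB = 0.0319, MDZL = 0.0266),
                          model = vpa_final_model(),
                          tau = 12, tid_prob = 0.4, lloq = 1,
                          time_jitter = 0) {
  stopifnot(n_subjects >= 1, abs(sum(obs_probs) - 1) < 1e-8,
            age_range[1] < age_mean, age_mean < age_range[2],
            dose_range[1] < dose_mean, dose_mean < dose_range[2],
            all(comed_probs >= 0 & comed_probs <= 1),
            inherits(model, "vpa_model"), tau > 0, lloq >= 0,
            tid_prob >= 0, tid_prob <= 1)
  age_pars <- solve_trunc_lnorm(age_mean, age_sd, age_range[1],
                                age_range[2])
  structure(list(n_subjects = n_subjects, obs_probs = obs_probs,
                 age_mean = age_mean, age_sd = age_sd,
                 age_range = age_range, age_pars = age_pars,
                 weight_cv = weight_cv, weight_range = weight_range,
                 dose_mean = dose_mean, dose_sd = dose_sd,
                 dose_range = dose_range, dose_round = dose_round,
                 snp_counts = snp_counts, comed_probs = comed_probs,
                 model = model, tau = tau, tid_prob = tid_prob,
                 lloq = lloq, time_jitter = time_jitter),
            class = "cohort_config")
}

# Sample genotype labels for one SNP under HWE.
sample_genotypes <- function(n, labels, counts) {
  p <- (2 * counts[1] + counts[2]) / (2 * sum(counts))
  sample(labels, n, replace = TRUE, prob = c(p^2, 2 * p * (1 - p),
                                             (1 - p)^2))
}

#' Generate a synthetic study dataset
#'
#' Draws a virtual cohort per the configuration and simulates steady-state
#' troughs from the generating model:
#' `DV = predict_trough(model, subject, eta_i) + eps` with
#' `eta_i ~ N(0, omega^2)` and residual noise from the model's error
#' specification. Fully reproducible from `seed`.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed; every draw in the generator flows from it.
#' @return Long-format data frame (one row per observation) with columns
#'   `ID`, `AGE`, `WT`, `SEX`, one column per SNP, one 0/1 column per
#'   co-medication, `DOSE_MG`, `II_H`, `TIME_H`, `DV`. The number of
#'   below-quantification redraws is attached as attribute
#'   `"n_lloq_resampled"`.
#' @export
generate_cohort <- function(config, seed = 1) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(seed)
  n <- config$n_subjects
  age <- rtrunc_lnorm(n, config$age_pars[["meanlog"]],
                      config$age_pars[["sdlog"]],
                      config$age_range[1], config$age_range[2])
  wt <- weight_for_age(age, clamp = c(-Inf, Inf)) *
    exp(stats::rnorm(n, 0, config$weight_cv))
  wt <- pmin(pmax(wt, config$weight_range[1]), config$weight_range[2])
  sex <- stats::rbinom(n, 1, 0.5)
  mgkgday <- rtrunc_norm(n, config$dose_mean, config$dose_sd,
                         config$dose_range[1], config$dose_range[2])
  tau_i <- ifelse(stats::runif(n) < config$tid_prob, 8, config$tau)
  dose_mg <- pmax(round(mgkgday * wt / (24 / tau_i) / config$dose_round) *
                    config$dose_round, config$dose_round)
  snp <- config$snp_counts
  geno <- lapply(seq_len(nrow(snp)), function(i) {
    labs <- strsplit(snp$genotype_labels[i], "/", fixed = TRUE)[[1]]
    sample_genotypes(n, labs, as.numeric(snp[i, c("n_1", "n_2", "n_3")]))
  })
  names(geno) <- snp$snp_id
  comeds <- lapply(config$comed_probs,
                   function(p) stats::rbinom(n, 1, p))
  obs_vals <- as.integer(names(config$obs_probs))
  n_obs <- obs_vals[sample.int(length(obs_vals), n, replace = TRUE,
                               prob = config$obs_probs)]

  subj <- data.frame(ID = seq_len(n), AGE = age, WT = wt, SEX = sex,
                     as.data.frame(geno), as.data.frame(comeds),
                     DOSE_MG = dose_mg, II_H = tau_i)
  long <- subj[rep(seq_len(n), n_obs), , drop = FALSE]
  rownames(long) <- NULL
  long$TIME_H <- long$II_H
  if (config$time_jitter > 0) {
    long$TIME_H <- pmin(pmax(long$II_H +
                               stats::rnorm(nrow(long), 0,
                                            config$time_jitter),
                             0.5), long$II_H)
  }
  model <- config$model
  eta <- stats::rnorm(n, 0, model$omega_cl)
  pred <- predict_trough(model, long, eta = eta[long$ID])
  draw_dv <- function(f) f + stats::rnorm(length(f)) * resid_sd(model$error, f)
  dv <- draw_dv(pred)
  n_resampled <- 0L
  for (i in 1:100) {
    low <- which(dv < config$lloq)
    if (length(low) == 0L) break
    n_resampled <- n_resampled + length(low)
    dv[low] <- draw_dv(pred[low])
  }
  dv[dv < config$lloq] <- config$lloq  # give up after 100 redraws
  long$DV <- dv
  attr(long, "n_lloq_resampled") <- n_resampled
  long
}

#' Independent replicate datasets
#'
#' `n_replicates` cohorts from the same configuration with seeds
#' `base_seed + 1, ..., base_seed + n_replicates`.
#'
#' @inheritParams generate_cohort
#' @param n_replicates number of datasets.
#' @param base_seed base of the per-replicate seeds.
#' @return List of data frames.
#' @export
generate_replicates <- function(config, n_replicates, base_seed = 0) {
  stopifnot(n_replicates >= 1)
  lapply(seq_len(n_replicates),
         function(i) generate_cohort(config, seed = base_seed + i))
}
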