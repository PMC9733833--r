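# Monte Carlo dose-optimization: probability of steady-state troughs
# falling in the 50-100 mg/L therapeutic window across virtual subgroups.

#' Probability of target attainment for one subgroup and dose
#'
#' Simulates `n` virtual children with ages uniform on `age_range`, weight
#' from the deterministic weight-for-age model, a fixed genotype, fresh
#' clearance random effects, and a twice-daily regimen delivering
#' `dose_mg_kg_day`; PTA is the percentage of steady-state troughs inside
#' the target window. Residual (assay) noise is excluded by default so the
#' PTA describes true trough exposure; set `include_residual = TRUE` to
#' describe measured concentrations instead.
#'
#' @param model a [vpa_model()] (usually [vpa_final_model()]).
#' @param age_range two ages in years, `[low, high)` of the subgroup bin.
#' @param genotype rs3789243 level (`"AA"`, `"AG"`, `"GG"`), or more
#'   generally a named list/vector of covariate values fixed for the
#'   subgroup.
#' @param dose_mg_kg_day total daily dose (mg/kg/day), split q12h.
#' @param target therapeutic window (mg/L), default 50-100.
#' @param n number of virtual subjects.
#' @param seed RNG seed.
#' @param tau dosing interval (h).
#' @param weight_model age -> weight function (kg).
#' @param include_residual add residual noise to the simulated troughs.
#' @param adequacy_pct PTA considered clinically acceptable.
#' @return One-row data.frame: `genotype`, `age_low`, `age_high`,
#'   `dose_mg_kg_day`, `n`, `pta_pct`, `adequate`.
#' @export
simulate_pta <- function(model, age_range, genotype = "AA",
                         dose_mg_kg_day, target = c(50, 100), n = 10000,
                         seed = 1, tau = 12,
                         weight_model = weight_for_age,
                         include_residual = FALSE, adequacy_pct = 70) {
  stopifnot(dose_mg_kg_day >= 0, target[1] < target[2], n >= 1,
            age_range[1] < age_range[2])
  set.seed(seed)
  age <- stats::runif(n, age_range[1], age_range[2])
  wt <- weight_model(age)
  dose <- dose_mg_kg_day * wt / (24 / tau)
  covs <- data.frame(AGE = age)
  if (is.character(genotype)) {
    covs$rs3789243 <- genotype
  } else {
    for (nm in names(genotype)) covs[[nm]] <- genotype[[nm]]
  }
  eta <- stats::rnorm(n, 0, model$omega_cl)
  cl <- individual_clearance(typical_clearance(model, covs), eta)
  trough <- conc_ss_(dose, tau, tau, cl, model$theta_v, model$ka)
  if (include_residual) {
    trough <- trough + stats::rnorm(n) * resid_sd(model$error, trough)
  }
  pta <- 100 * mean(trough >= target[1] & trough <= target[2])
  data.frame(genotype = if (is.character(genotype)) genotype else NA,
             age_low = age_range[1], age_high = age_range[2],
             dose_mg_kg_day = dose_mg_kg_day, n = n, pta_pct = pta,
             adequate = pta >= adequacy_pct)
}

#' PTA grid over genotype, age bin and dose
#'
#' One [simulate_pta()] cell per combination; deterministic given `seed`
#' (each cell uses an independent sub-seed).
#'
#' @inheritParams simulate_pta
#' @param genotypes rs3789243 levels to simulate.
#' @param age_bins list of two-element age ranges (years).
#' @param doses daily doses (mg/kg/day).
#' @return Data frame of PTA cells with adequacy flags.
#' @export
pta_table <- function(model, genotypes = c("AA", "AG", "GG"),
                      age_bins = list(c(1, 2), c(2, 3), c(3, 4), c(4, 6),
                                      c(6, 8), c(8, 10), c(10, 12)),
                      doses = c(15, 20, 25, 30, 35), target = c(50, 100),
                      n = 10000, seed = 1, tau = 12,
                      weight_model = weight_for_age,
                      include_residual = FALSE, adequacy_pct = 70) {
  stopifnot(length(genotypes) >= 1, length(age_bins) >= 1,
            length(doses) >= 1)
  cells <- list()
  k <- 0L
  for (g in genotypes) {
    for (b in seq_along(age_bins)) {
      for (d in doses) {
        k <- k + 1L
        cells[[k]] <- simulate_pta(model, age_bins[[b]], g, d,
                                   target = target, n = n,
                                   seed = (seed * 100003 + k) %% 2147483647, tau = tau,
                                   weight_model = weight_model,
                                   include_residual = include_residual,
                                   adequacy_pct = adequacy_pct)
      }
    }
  }
  do.call(rbind, cells)
}

#' Minimal adequate dose per subgroup
#'
#' From a PTA table, the smallest dose whose PTA meets the threshold in
#' each (genotype, age bin) subgroup (`rule = "minimal"`); with
#' `rule = "max_pta"` the dose with the highest PTA among the adequate
#' ones, the reading under which a higher-clearance genotype can be pushed
#' to a higher recommended dose. `NA` with `none_adequate = TRUE` when no
#' dose reaches the threshold.
#'
#' @param pta data frame as returned by [pta_table()] (any table with
#'   `genotype`, `age_low`, `age_high`, `dose_mg_kg_day`, `pta_pct`).
#' @param threshold_pct clinical acceptability threshold.
#' @param rule `"minimal"` (default) or `"max_pta"`.
#' @return Data frame with one row per subgroup: recommended
#'   `dose_mg_kg_day` (NA if none), its `pta_pct`, `none_adequate`.
#' @export
recommend_dose <- function(pta, threshold_pct = 70,
                           rule = c("minimal", "max_pta")) {
  rule <- match.arg(rule)
  need <- c("genotype", "age_low", "age_high", "dose_mg_kg_day",
            "pta_pct")
  stopifnot(all(need %in% names(pta)))
  key <- interaction(pta$genotype, pta$age_low, pta$age_high, drop = TRUE)
  out <- lapply(split(pta, key), function(grp) {
    ad <- grp[grp$pta_pct >= threshold_pct, , drop = FALSE]
    if (nrow(ad) == 0L) {
      data.frame(genotype = grp$genotype[1], age_low = grp$age_low[1],
                 age_high = grp$age_high[1], dose_mg_kg_day = NA_real_,
                 pta_pct = NA_real_, none_adequate = TRUE)
    } else {
      pick <- switch(rule,
                     minimal = ad[which.min(ad$dose_mg_kg_day), ],
                     max_pta = ad[which.max(ad$pta_pct), ])
      data.frame(genotype = pick$genotype, age_low = pick$age_low,
                 age_high = pick$age_high,
                 dose_mg_kg_day = pick$dose_mg_kg_day,
                 pta_pct = pick$pta_pct, none_adequate = FALSE)
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$genotype, res$age_low), ]
}

#' Simulated steady-state trough versus body weight
#'
#' Simulates troughs for typical children of 10-40 kg at each
#' (weight, dose mg/kg/day) cell and reports their mean and SD; cells
#' whose mean exceeds the upper bound of the therapeutic window are
#' flagged as toxicity risks. By default the virtual patient is a typical
#' child (fixed reference age, hence fixed typical clearance) and weight
#' only scales the absolute dose, so the mean trough rises strictly with
#' weight; `age_from_weight = TRUE` instead derives age from the inverse
#' weight-for-age rule, coupling clearance to weight.
#'
#' @inheritParams simulate_pta
#' @param weights body weights (kg).
#' @param doses daily doses (mg/kg/day).
#' @param age_y age (years) of the typical virtual patient.
#' @param age_from_weight derive age from weight via [age_for_weight()]
#'   instead of holding it fixed.
#' @param toxic_above concentration (mg/L) above which the mean trough is
#'   flagged.
#' @return Data frame: `weight_kg`, `age_y`, `dose_mg_kg_day`,
#'   `mean_trough`, `sd_trough`, `exceeds_toxic`.
#' @export
trough_vs_weight <- function(model, weights = seq(10, 40, by = 2),
                             doses = c(20, 30, 40), genotype = "AA",
                             age_y = 5, age_from_weight = FALSE,
                             n = 2000, seed = 1, tau = 12,
                             toxic_above = 100) {
  cells <- list()
  k <- 0L
  for (w in weights) {
    age <- if (age_from_weight) age_for_weight(w) else age_y
    for (d in doses) {
      k <- k + 1L
      set.seed((seed * 100003 + k) %% 2147483647)
      eta <- stats::rnorm(n, 0, model$omega_cl)
      covs <- data.frame(AGE = rep(age, n), rs3789243 = genotype)
      cl <- individual_clearance(typical_clearance(model, covs), eta)
      trough <- conc_ss_(d * w / (24 / tau), tau, tau, cl, model$theta_v,
                         model$ka)
      cells[[k]] <- data.frame(weight_kg = w, age_y = age,
                               dose_mg_kg_day = d,
                               mean_trough = mean(trough),
                               sd_trough = stats::sd(trough),
                               exceeds_toxic = mean(trough) > toxic_above)
    }
  }
  do.call(rbind, cells)
}
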