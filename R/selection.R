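# Stepwise covariate search on CL/F: forward inclusion by the largest
# significant OFV drop, backward elimination at a stricter level, with a
# per-candidate trace of every hypothesis test.

comed_codes <- c("LEV", "OXC", "TPM", "CNZ", "PB", "MDZL", "IBU")

#' Add the derived daily-dose covariate
#'
#' Adds `TDD`, the total valproic acid daily dose in mg/kg/day
#' (`DOSE_MG * (24 / II_H) / WT`), when absent.
#'
#' @param data long-format dataset.
#' @return The dataset with a `TDD` column.
#' @export
derive_tdd <- function(data) {
  if (!"TDD" %in% names(data)) {
    data$TDD <- data$DOSE_MG * (24 / data$II_H) / data$WT
  }
  data
}

# Subject-level genotype counts for one SNP column, ordered
# major-homozygote, heterozygote, minor-homozygote.
genotype_counts_from_data <- function(data, snp) {
  g <- as.character(data[[snp]][!duplicated(data$ID)])
  alleles <- sort(unique(unlist(strsplit(g, ""))))
  if (length(alleles) > 2) stop("SNP ", snp, " is not biallelic")
  if (length(alleles) == 1) alleles <- c(alleles, alleles)
  n1 <- sum(g == paste0(alleles[1], alleles[1]))
  het <- sum(!g %in% paste0(alleles, alleles))
  n2 <- sum(g == paste0(alleles[2], alleles[2]))
  if (2 * n2 + het > 2 * n1 + het) {
    alleles <- rev(alleles)
    tmp <- n1; n1 <- n2; n2 <- tmp
  }
  hets <- setdiff(unique(g), paste0(alleles, alleles))
  het_label <- if (length(hets)) hets[1] else
    paste0(alleles[1], alleles[2])
  list(labels = c(paste0(alleles[1], alleles[1]), het_label,
                  paste0(alleles[2], alleles[2])),
       counts = c(n1, het, n2))
}

new_candidate <- function(name, kind, forms, ref = NULL, levels = NULL) {
  structure(list(name = name, kind = kind, forms = forms, ref = ref,
                 levels = levels),
            class = "vpa_candidate")
}

#' Screen a dataset for admissible covariates on CL/F
#'
#' Builds the candidate list for the stepwise search: the continuous
#' covariates age, weight and daily dose; sex; co-medications given to more
#' than `comed_threshold` of the samples (rarer drugs carry no power and
#' are dropped); and every SNP column whose subject-level genotype counts
#' conform to Hardy-Weinberg equilibrium at level `hwe_alpha`
#' (see [hwe_chisq()]). Genotypes enter as three-level categorical
#' covariates with the major-allele homozygote as reference.
#'
#' @param data long-format dataset.
#' @param comed_threshold minimum fraction of observation rows with the
#'   co-medication flag set.
#' @param hwe_alpha equilibrium exclusion level for SNPs.
#' @param continuous_forms functional forms tried for continuous
#'   covariates (subset of `"linear"`, `"power"`, `"exponential"`,
#'   `"piecewise"`).
#' @param age_ref,wt_ref centering values for age (y) and weight (kg);
#'   daily dose is centred at its subject-level median.
#' @return List of candidate descriptors, plus attributes
#'   `"excluded_comeds"` and `"excluded_snps"`.
#' @export
screen_candidates <- function(data, comed_threshold = 0.025,
                              hwe_alpha = 0.05,
                              continuous_forms = "power",
                              age_ref = 5, wt_ref = 20) {
  data <- derive_tdd(data)
  cands <- list()
  subj <- data[!duplicated(data$ID), , drop = FALSE]
  if ("AGE" %in% names(data)) {
    cands <- c(cands, list(new_candidate("AGE", "continuous",
                                         continuous_forms, ref = age_ref)))
  }
  if ("WT" %in% names(data)) {
    cands <- c(cands, list(new_candidate("WT", "continuous",
                                         continuous_forms, ref = wt_ref)))
  }
  cands <- c(cands, list(new_candidate("TDD", "continuous",
                                       continuous_forms,
                                       ref = stats::median(subj$TDD))))
  if ("SEX" %in% names(data)) {
    cands <- c(cands, list(new_candidate("SEX", "categorical", "multiplier",
                                         levels = c("0", "1"))))
  }
  comeds <- intersect(comed_codes, names(data))
  comed_prop <- vapply(comeds, function(cm) mean(data[[cm]] == 1), 0)
  kept_comeds <- comeds[comed_prop >= comed_threshold]
  for (cm in kept_comeds) {
    cands <- c(cands, list(new_candidate(cm, "categorical", "multiplier",
                                         levels = c("0", "1"))))
  }
  snps <- grep("^rs[0-9]+$", names(data), value = TRUE)
  excluded_snps <- character()
  for (s in snps) {
    gc <- genotype_counts_from_data(data, s)
    hw <- suppressWarnings(hwe_chisq(gc$counts, snp_id = s,
                                     labels = gc$labels,
                                     alpha = hwe_alpha))
    if (hw$in_hwe) {
      lv <- gc$labels[gc$counts > 0 | seq_along(gc$labels) == 1L]
      cands <- c(cands, list(new_candidate(s, "categorical", "multiplier",
                                           levels = lv)))
    } else {
      excluded_snps <- c(excluded_snps, s)
    }
  }
  attr(cands, "excluded_comeds") <- comeds[comed_prop < comed_threshold]
  attr(cands, "excluded_snps") <- excluded_snps
  cands
}

# Attach a null-effect covariate term for a candidate to a model.
add_candidate_term <- function(model, cand, form) {
  term <- if (cand$kind == "categorical") {
    nonref <- setdiff(cand$levels, cand$levels[1])
    cov_multiplier(cand$name, ref_level = cand$levels[1],
                   multipliers = stats::setNames(rep(1, length(nonref)),
                                                 nonref))
  } else {
    switch(form,
           linear = cov_linear(cand$name, 0, cand$ref),
           power = cov_power(cand$name, 0, cand$ref),
           exponential = cov_exponential(cand$name, 0, cand$ref),
           piecewise = cov_piecewise(cand$name, 0, 0, cand$ref),
           stop("unknown form ", form))
  }
  model$covariates <- c(model$covariates, list(term))
  model
}

remove_covariate <- function(model, name) {
  keep <- vapply(model$covariates, function(ct) ct$covariate != name, TRUE)
  model$covariates <- model$covariates[keep]
  model
}

term_df <- function(term) {
  switch(term$form, multiplier = length(term$coef),
         piecewise = 2L, 1L)
}

step_record <- function(action, covariate, form, df, ofv_before, ofv_after,
                        threshold, accepted, converged = TRUE) {
  data.frame(step_index = NA_integer_, action = action,
             covariate = covariate, form = form, df = df,
             ofv_before = ofv_before, ofv_after = ofv_after,
             delta_ofv = ofv_after - ofv_before, threshold = threshold,
             accepted = accepted, converged = converged,
             stringsAsFactors = FALSE)
}

#' One forward-inclusion step
#'
#' Fits every candidate-by-form extension of the current model and accepts
#' the one with the largest OFV drop exceeding the chi-squared criterion
#' `qchisq(1 - alpha, df)` for its degrees of freedom (3.84 for a 1-df term
#' at `alpha = 0.05`). Ties are broken by lower AIC, then fewer parameters,
#' then name. Candidates whose fit fails to converge are skipped and
#' flagged in the trace.
#'
#' @param fit current [vpa_fit()] (its data are reused).
#' @param candidates list from [screen_candidates()].
#' @param alpha forward inclusion level.
#' @param flat_threshold optional fixed OFV-change criterion applied to
#'   every candidate regardless of df (e.g. 3.84), overriding the
#'   chi-squared scaling.
#' @return List with `accepted` (logical), `fit` (updated or unchanged),
#'   `candidate` (name or NA) and `trace` (one row per hypothesis test).
#' @export
forward_step <- function(fit, candidates, alpha = 0.05,
                         flat_threshold = NULL) {
  stopifnot(inherits(fit, "vpa_fit"))
  data <- derive_tdd(fit$data)
  trials <- list()
  best <- NULL
  for (cand in candidates) {
    for (form in cand$forms) {
      m2 <- add_candidate_term(fit$model, cand, form)
      df <- term_df(m2$covariates[[length(m2$covariates)]])
      thr <- if (is.null(flat_threshold)) {
        stats::qchisq(1 - alpha, df)
      } else flat_threshold
      f2 <- tryCatch(
        vpa_fit(m2, data, fixed = fit$fixed, engine = fit$engine,
                nodes = fit$nodes, compute_se = FALSE),
        error = function(e) NULL)
      if (is.null(f2) || !f2$converged) {
        trials[[length(trials) + 1L]] <-
          step_record("add", cand$name, form, df, fit$ofv, NA_real_, thr,
                      FALSE, converged = FALSE)
        next
      }
      acc_ok <- (fit$ofv - f2$ofv) > thr
      trials[[length(trials) + 1L]] <-
        step_record("add", cand$name, form, df, fit$ofv, f2$ofv, thr,
                    FALSE)
      if (acc_ok) {
        key <- list(drop = fit$ofv - f2$ofv, aic = f2$aic,
                    p = f2$n_params, name = cand$name)
        better <- is.null(best) ||
          key$drop > best$key$drop + 1e-9 ||
          (abs(key$drop - best$key$drop) <= 1e-9 &&
             (key$aic < best$key$aic - 1e-9 ||
                (abs(key$aic - best$key$aic) <= 1e-9 &&
                   (key$p < best$key$p ||
                      (key$p == best$key$p && key$name < best$key$name)))))
        if (better) {
          best <- list(fit = f2, key = key, form = form,
                       trial = length(trials))
        }
      }
    }
  }
  trace <- do.call(rbind, trials)
  if (is.null(best)) {
    trace <- rbind(trace,
                   step_record("stop", NA_character_, NA_character_, NA,
                               fit$ofv, fit$ofv, NA_real_, FALSE))
    return(list(accepted = FALSE, fit = fit, candidate = NA_character_,
                trace = trace))
  }
  trace$accepted[best$trial] <- TRUE
  list(accepted = TRUE, fit = best$fit, candidate = best$key$name,
       trace = trace)
}

#' One backward-elimination step
#'
#' Removes each covariate term in turn and refits; a term whose removal
#' raises the OFV by less than `qchisq(1 - alpha, df)` (6.63 for 1 df at
#' the conventional stricter backward level `alpha = 0.01`) is not
#' supported by the data, and the least supported such term is eliminated.
#'
#' @param fit current [vpa_fit()].
#' @param alpha backward elimination level.
#' @param flat_threshold optional fixed criterion overriding the
#'   chi-squared scaling.
#' @return Same structure as [forward_step()], with `action = "remove"`
#'   rows.
#' @export
backward_step <- function(fit, alpha = 0.01, flat_threshold = NULL) {
  stopifnot(inherits(fit, "vpa_fit"))
  if (length(fit$model$covariates) == 0L) {
    return(list(accepted = FALSE, fit = fit, candidate = NA_character_,
                trace = step_record("stop", NA_character_, NA_character_,
                                    NA, fit$ofv, fit$ofv, NA_real_,
                                    FALSE)))
  }
  data <- derive_tdd(fit$data)
  trials <- list()
  best <- NULL
  for (ct in fit$model$covariates) {
    df <- term_df(ct)
    thr <- if (is.null(flat_threshold)) stats::qchisq(1 - alpha, df)
           else flat_threshold
    m2 <- remove_covariate(fit$model, ct$covariate)
    f2 <- tryCatch(
      vpa_fit(m2, data, fixed = fit$fixed, engine = fit$engine,
              nodes = fit$nodes, compute_se = FALSE),
      error = function(e) NULL)
    if (is.null(f2) || !f2$converged) {
      trials[[length(trials) + 1L]] <-
        step_record("remove", ct$covariate, ct$form, df, fit$ofv,
                    NA_real_, thr, FALSE, converged = FALSE)
      next
    }
    rise <- f2$ofv - fit$ofv
    trials[[length(trials) + 1L]] <-
      step_record("remove", ct$covariate, ct$form, df, fit$ofv, f2$ofv,
                  thr, FALSE)
    if (rise < thr && (is.null(best) || rise < best$rise)) {
      best <- list(fit = f2, rise = rise, name = ct$covariate,
                   trial = length(trials))
    }
  }
  trace <- do.call(rbind, trials)
  if (is.null(best)) {
    trace <- rbind(trace,
                   step_record("stop", NA_character_, NA_character_, NA,
                               fit$ofv, fit$ofv, NA_real_, FALSE))
    return(list(accepted = FALSE, fit = fit, candidate = NA_character_,
                trace = trace))
  }
  trace$accepted[best$trial] <- TRUE
  list(accepted = TRUE, fit = best$fit, candidate = best$name,
       trace = trace)
}

#' Stepwise forward-inclusion / backward-elimination covariate search
#'
#' Starting from a base model, adds covariates one at a time by
#' [forward_step()] until no candidate meets the inclusion criterion, then
#' prunes by [backward_step()] until every remaining term survives the
#' stricter elimination criterion. A term eliminated backwards is not
#' re-offered, which guarantees termination. Deterministic given the data.
#'
#' @param model base [vpa_model()] (initial estimates).
#' @param data long-format dataset.
#' @param candidates list from [screen_candidates()]; an empty list returns
#'   the base fit with a single stop record.
#' @param forward_alpha,backward_alpha inclusion / elimination levels.
#' @param flat_threshold optional fixed OFV criterion for both directions.
#' @param fixed,engine,nodes passed to [vpa_fit()].
#' @return List with `fit` (final model fit), `selected` (covariate names)
#'   and `trace` (the full hypothesis-testing table; accepted steps carry
#'   consecutive `step_index`).
#' @export
run_stepwise <- function(model, data, candidates, forward_alpha = 0.05,
                         backward_alpha = 0.01, flat_threshold = NULL,
                         fixed = character(), engine = "agq", nodes = 21) {
  data <- derive_tdd(data)
  fit <- vpa_fit(model, data, fixed = fixed, engine = engine,
                 nodes = nodes, compute_se = FALSE)
  if (!fit$converged) stop("base model fit did not converge")
  pool <- candidates
  traces <- list()
  step_i <- 0L
  if (length(pool) == 0L) {
    tr <- step_record("stop", NA_character_, NA_character_, NA, fit$ofv,
                      fit$ofv, NA_real_, FALSE)
    return(list(fit = fit, selected = character(), trace = tr))
  }
  repeat {
    if (length(pool) == 0L) break
    fs <- forward_step(fit, pool, alpha = forward_alpha,
                       flat_threshold = flat_threshold)
    if (fs$accepted) step_i <- step_i + 1L
    fs$trace$step_index <- step_i
    traces[[length(traces) + 1L]] <- fs$trace
    if (!fs$accepted) break
    fit <- fs$fit
    pool <- Filter(function(cd) cd$name != fs$candidate, pool)
  }
  repeat {
    bs <- backward_step(fit, alpha = backward_alpha,
                        flat_threshold = flat_threshold)
    if (bs$accepted) step_i <- step_i + 1L
    bs$trace$step_index <- step_i
    traces[[length(traces) + 1L]] <- bs$trace
    if (!bs$accepted) break
    fit <- bs$fit
  }
  selected <- vapply(fit$model$covariates, `[[`, "", "covariate")
  list(fit = fit, selected = selected, trace = do.call(rbind, traces))
}
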