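# Covariate screening and the stepwise OFV-based search.

# Dataset with controlled co-medication proportions and genotype counts.
screening_dataset <- function() {
  d <- default_cohort()
  subj_of <- match(d$ID, unique(d$ID))
  # rare drug on ~1.6% of sample rows, common drug well above threshold
  d$IBU <- 0
  d$IBU[seq_len(ceiling(0.016 * nrow(d)))] <- 1
  d$LEV <- as.integer(subj_of <= 20)
  # overwrite two SNPs with the panel's exact subject-level counts
  d$rs3789243 <- rep(c("AA", "AG", "GG"), c(14, 50, 39))[subj_of]
  d$rs1057910 <- rep(c("AA", "AC", "CC"), c(96, 6, 1))[subj_of]
  d
}

test_that("screening drops rare co-medications and disequilibrium SNPs", {
  d <- screening_dataset()
  cands <- screen_candidates(d)
  nm <- vapply(cands, `[[`, "", "name")
  expect_false("IBU" %in% nm)
  expect_true("LEV" %in% nm)
  expect_true("rs3789243" %in% nm)
  expect_false("rs1057910" %in% nm)
  expect_true("rs1057910" %in% attr(cands, "excluded_snps"))
  expect_true(all(c("AGE", "WT", "TDD") %in% nm))
  # no filter at threshold zero
  nm0 <- vapply(screen_candidates(d, comed_threshold = 0), `[[`, "",
                "name")
  expect_true("IBU" %in% nm0)
  # genotype reference level is the major-allele homozygote
  geno <- cands[[which(nm == "rs3789243")]]
  expect_identical(geno$levels[1], "GG")  # G is the major allele here
})

test_that("forward inclusion obeys its stopping rule at extreme thresholds", {
  d <- generate_cohort(cohort_config(n_subjects = 25), seed = 13)
  f0 <- vpa_fit(vpa_base_model(), d, compute_se = FALSE)
  cand_age <- screen_candidates(d)
  cand_age <- cand_age[vapply(cand_age, `[[`, "", "name") == "AGE"]
  blocked <- forward_step(f0, cand_age, flat_threshold = Inf)
  expect_false(blocked$accepted)
  expect_identical(blocked$fit$ofv, f0$ofv)
  expect_identical(blocked$trace$action[nrow(blocked$trace)], "stop")
  always <- forward_step(f0, cand_age, flat_threshold = 0)
  expect_true(always$accepted)
  expect_lt(always$fit$ofv, f0$ofv)
})

test_that("stepwise trace is internally consistent and respects degrees of freedom", {
  d <- generate_cohort(cohort_config(n_subjects = 60), seed = 17)
  cands <- screen_candidates(d)
  keep <- vapply(cands, `[[`, "", "name") %in% c("AGE", "WT", "rs3789243")
  res <- run_stepwise(vpa_base_model(), d, cands[keep])
  tr <- res$trace
  expect_true("AGE" %in% res$selected)
  # age and weight are nearly collinear; both must never survive together
  expect_false(all(c("AGE", "WT") %in% res$selected))
  # accepted steps chain: each accepted ofv_after is the next ofv_before
  acc <- tr[tr$accepted %in% TRUE, ]
  if (nrow(acc) > 1) {
    expect_equal(acc$ofv_after[-nrow(acc)],
                 acc$ofv_before[-1], tolerance = 1e-6)
  }
  expect_equal(tr$delta_ofv, tr$ofv_after - tr$ofv_before,
               tolerance = 1e-9)
  # a two-level genotype term carries 2 df and the matching threshold
  g <- tr[tr$covariate %in% "rs3789243" & tr$action == "add", ]
  expect_true(all(g$df == 2))
  expect_equal(g$threshold, rep(qchisq(0.95, 2), nrow(g)))
})

test_that("an empty candidate list returns the base fit with a stop record", {
  d <- generate_cohort(cohort_config(n_subjects = 20), seed = 19)
  res <- run_stepwise(vpa_base_model(), d, list())
  expect_identical(res$selected, character(0))
  expect_identical(res$trace$action, "stop")
})

test_that("removing the age term from the final model costs a large OFV increase", {
  f <- default_fit()
  no_age <- vpa_model(theta_cl = 0.214, theta_v = 3.63,
                      covariates = list(
                        cov_multiplier("rs3789243", "AA",
                                       c(AG = 0.953, GG = 1.08))),
                      omega_cl = 0.3,
                      error = vpa_error("additive", sigma_add = 13))
  f0 <- vpa_fit(no_age, default_cohort(), compute_se = FALSE)
  expect_gt(f0$ofv - f$ofv, 50)
})
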