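#' Hardy-Weinberg equilibrium chi-square test for one biallelic SNP
#'
#' Allele frequencies are obtained by gene counting from the three genotype
#' counts (first homozygote, heterozygote, second homozygote); expected
#' counts are `n*p^2`, `2npq`, `n*q^2` and the Pearson chi-square statistic
#' is referred to a chi-squared distribution with 1 df. No continuity
#' correction and no exact test are applied: with sparse genotypes
#' (expected count below 5) a warning is emitted but the asymptotic test is
#' still reported, the convention under which the screen's reference
#' p-values were produced. A monomorphic SNP (one allele absent) is in
#' equilibrium by construction: `chi2 = 0`, `p = 1`.
#'
#' @param counts integer vector of length 3: homozygote, heterozygote,
#'   homozygote counts.
#' @param snp_id optional identifier carried into the result.
#' @param labels optional genotype labels (length 3).
#' @param alpha significance level for the `in_hwe` flag.
#' @return List of class `hwe_result`: `snp_id`, `labels`, `counts`,
#'   `allele_freqs`, `expected`, `chi2`, `p_value`, `in_hwe`,
#'   `monomorphic`.
#' @examples
#' hwe_chisq(c(14, 50, 39), snp_id = "rs3789243")$p_value  # ~0.748
#' @export
hwe_chisq <- function(counts, snp_id = NA_character_, labels = NULL,
                      alpha = 0.05) {
  stopifnot(length(counts) == 3L, all(counts >= 0), sum(counts) >= 1)
  n <- sum(counts)
  p <- (2 * counts[1] + counts[2]) / (2 * n)
  q <- 1 - p
  expected <- n * c(p^2, 2 * p * q, q^2)
  mono <- p == 0 || q == 0
  if (mono) {
    chi2 <- 0
    pval <- 1
  } else {
    if (any(expected < 5)) {
      warning(sprintf(
        "SNP %s: expected genotype count below 5 (min %.2f); asymptotic chi-square may be unreliable",
        snp_id, min(expected)), call. = FALSE)
    }
    chi2 <- sum((counts - expected)^2 / expected)
    pval <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  }
  structure(list(snp_id = snp_id, labels = labels, counts = counts,
                 allele_freqs = c(p, q), expected = expected,
                 chi2 = chi2, p_value = pval, in_hwe = pval > alpha,
                 monomorphic = mono),
            class = "hwe_result")
}

#' @export
print.hwe_result <- function(x, ...) {
  cat(sprintf("HWE %s: counts %s, p(allele1) %.3f, chi2 %.4f, p %.4g%s\n",
              x$snp_id, paste(x$counts, collapse = "/"),
              x$allele_freqs[1], x$chi2, x$p_value,
              if (x$monomorphic) " (monomorphic)" else ""))
  invisible(x)
}

#' Genotype frequencies in percent
#'
#' @param counts non-negative genotype counts.
#' @return `100 * counts / sum(counts)`; sums to 100 exactly before any
#'   rounding.
#' @export
genotype_freqs <- function(counts) {
  stopifnot(sum(counts) >= 1)
  100 * counts / sum(counts)
}

#' Screen a panel of SNPs for Hardy-Weinberg equilibrium
#'
#' Runs [hwe_chisq()] on every row of a counts table and partitions the
#' SNPs into those conforming to equilibrium (`p > alpha`) and those
#' excluded from covariate testing.
#'
#' @param counts_table data frame with columns `snp_id`, `n_1`, `n_2`,
#'   `n_3` (and optionally `genotype_labels` as `"AA/AG/GG"` strings), such
#'   as [vpa_snp_counts()].
#' @param alpha exclusion level; `alpha = 0` retains everything.
#' @return List with `retained`, `excluded` (character vectors of SNP ids)
#'   and `results`, a data frame with counts, frequencies, chi-square and
#'   p-value per SNP.
#' @export
hwe_screen <- function(counts_table, alpha = 0.05) {
  stopifnot(all(c("snp_id", "n_1", "n_2", "n_3") %in% names(counts_table)),
            nrow(counts_table) >= 1)
  res <- lapply(seq_len(nrow(counts_table)), function(i) {
    cnt <- as.numeric(counts_table[i, c("n_1", "n_2", "n_3")])
    labs <- if ("genotype_labels" %in% names(counts_table)) {
      strsplit(counts_table$genotype_labels[i], "/", fixed = TRUE)[[1]]
    } else NULL
    hwe_chisq(cnt, snp_id = counts_table$snp_id[i], labels = labs,
              alpha = alpha)
  })
  freqs <- t(vapply(res, function(r) genotype_freqs(r$counts),
                    numeric(3)))
  tab <- data.frame(
    snp_id = vapply(res, `[[`, "", "snp_id"),
    n_1 = vapply(res, function(r) r$counts[1], 0),
    n_2 = vapply(res, function(r) r$counts[2], 0),
    n_3 = vapply(res, function(r) r$counts[3], 0),
    freq_1_pct = freqs[, 1], freq_2_pct = freqs[, 2],
    freq_3_pct = freqs[, 3],
    allele1_freq = vapply(res, function(r) r$allele_freqs[1], 0),
    chi2 = vapply(res, `[[`, 0, "chi2"),
    p_value = vapply(res, `[[`, 0, "p_value"),
    in_hwe = vapply(res, `[[`, TRUE, "in_hwe"))
  list(retained = tab$snp_id[tab$in_hwe],
       excluded = tab$snp_id[!tab$in_hwe],
       results = tab)
}

#' Genotype counts of the study SNP panel
#'
#' The 15-SNP pharmacogenetic panel (ABC transporters, metabolic enzymes,
#' sodium-channel genes) with genotype counts observed in the 103-patient
#' cohort, as shipped in `inst/extdata/snp_genotype_counts.csv`. Used both
#' as the reference input of the equilibrium screen and to derive allele
#' frequencies for the synthetic cohort generator.
#'
#' @return Data frame with `gene`, `snp_id`, `genotype_labels`, `n_1`,
#'   `n_2`, `n_3`.
#' @export
vpa_snp_counts <- function() {
  path <- system.file("extdata", "snp_genotype_counts.csv",
                      package = "vpapk", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
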