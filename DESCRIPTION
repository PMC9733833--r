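Package: vpapk
Title: Population Pharmacokinetics and Dose Optimization of Valproic Acid in
    Children
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Nonlinear mixed-effects population-pharmacokinetic modelling of
    steady-state valproic acid trough concentrations in pediatric epilepsy.
    Provides a one-compartment oral steady-state structural model with
    covariate-dependent apparent clearance, exact marginal-likelihood
    estimation by adaptive Gauss-Hermite quadrature (with a FOCE-I style
    linearized engine for comparison), stepwise covariate selection by
    objective-function change, bootstrap and visual-predictive-check model
    evaluation, Hardy-Weinberg equilibrium screening of pharmacogenetic
    covariates, Monte Carlo probability-of-target-attainment dose simulation,
    and a synthetic cohort generator mirroring the demographic, dosing and
    genotype structure of a pediatric valproic acid TDM population.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
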