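# vpapk

Population pharmacokinetics and dose optimization of valproic acid (VPA)
in children with epilepsy.

VPA has a narrow therapeutic window (50–100 mg/L) and notoriously variable
kinetics in children, so dosing is steered by therapeutic drug monitoring
of steady-state trough concentrations. `vpapk` implements the full
modelling pipeline around such trough data: a one-compartment oral
steady-state structural model whose apparent clearance depends on age and
the *ABCB1* rs3789243 genotype, exact nonlinear mixed-effects estimation,
stepwise covariate selection, bootstrap and visual-predictive-check
evaluation, Hardy–Weinberg screening of pharmacogenetic covariates, and
Monte Carlo probability-of-target-attainment (PTA) dose tables — plus a
synthetic cohort generator that reproduces the statistical structure of a
103-child TDM population so everything is testable end to end.

## The model

Steady-state concentration after repeated oral dosing (dose `D` every
`τ` h, evaluated `t` h after a dose):

```
C(t) = D·ka / (V/F·(ka − ke)) · [ e^(−ke·t)/(1 − e^(−ke·τ)) − e^(−ka·t)/(1 − e^(−ka·τ)) ],
ke = (CL/F)/(V/F),  ka fixed at 1.9 h⁻¹
```

with a hierarchical clearance model

```
CL/F = θ_CL · (AGE/5)^θ_age · θ_AG^[AG] · θ_GG^[GG] · exp(η),  η ~ N(0, ω²)
```

(final estimates: θ_CL 0.214 L/h, θ_age 0.357, θ_AG 0.953, θ_GG 1.08,
V/F 3.63 L, ω 0.169, additive residual σ 11.9 mg/L). The per-subject
marginal likelihood is a one-dimensional integral over η and is computed
by adaptive Gauss–Hermite quadrature centred at the conditional mode; a
FOCE-I-style linearized engine is included for comparison.

## Worked example

```r
library(vpapk)

# a synthetic study cohort: 103 children, ~376 steady-state troughs
cohort <- generate_cohort(cohort_config(), seed = 42)

# refit the final covariate model from neutral starting values
start <- vpa_model(theta_cl = 0.15, theta_v = 3, ka = 1.9,
                   covariates = list(
                     cov_power("AGE", 0.2, ref = 5),
                     cov_multiplier("rs3789243", "AA", c(AG = 1, GG = 1))),
                   omega_cl = 0.25,
                   error = vpa_error("additive", sigma_add = 10))
fit <- vpa_fit(start, cohort)
fit
#> Population-PK fit (agq engine): 103 subjects, 385 observations
#>   OFV 3181.617 | AIC 3195.617 | BIC 3223.290 | converged
#>                   estimate rse_pct
#> theta_cl            0.2136   14.90
#> theta_v             3.4070   51.90
#> beta_AGE            0.3172   12.40
#> mult_rs3789243_AG   0.9176    6.59
#> mult_rs3789243_GG   1.0410    6.41
#> omega_cl            0.1771   13.60
#> sigma_add          11.7000    4.25
#>   eta-shrinkage 9.9% | eps-shrinkage 11.4%
```

One replicate recovers the generating values (0.214 L/h, 3.63 L, 0.357,
0.953, 1.08, 0.169, 11.9) to within sampling error: a five-year-old AA
child clears ~0.21 L/h, a GG child about 4–8% more, an AG child a few
percent less. The apparent volume is the weakly identified parameter of a
trough-only design (note its RSE); medians over replicate cohorts, which
is what `scripts/acceptance.R` reports, pin all parameters down tightly.
From the fitted model:

```r
# Hardy–Weinberg screen of the 15-SNP panel: 12 retained, 3 excluded
hwe_screen(vpa_snp_counts())

# dose tables: percent of virtual patients with troughs in 50–100 mg/L
tab <- pta_table(fit$model, n = 10000, seed = 1)
recommend_dose(tab, threshold_pct = 70)   # minimal adequate mg/kg/day

# evaluation
boot <- vpa_bootstrap(fit, n_runs = 200, seed = 1)
vpc <- vpa_vpc(fit, n_sim = 1000, seed = 1, binning = "age")
```

See `vignettes/valproic-poppk-methods.Rmd` for the model's assumptions,
the estimation machinery, and the design decisions (including why
attainment orderings invert below age three under this clearance model).

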