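---
title: "Methods: population pharmacokinetics of valproic acid in children"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population pharmacokinetics of valproic acid in children}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`vpapk` models steady-state trough concentrations of valproic acid (VPA)
in epileptic children and turns the fitted population model into dosing
guidance. This vignette is the package's own account of the science: the
hierarchical model and its assumptions, the estimation machinery, the
covariate search, the evaluation tools, the Monte Carlo dose simulation,
and the synthetic cohort generator that stands in for patient data —
together with the numerical choices and their rationale.

## The model

VPA given orally two to three times a day is described by a one-compartment
model with first-order absorption and elimination. Because only pre-dose
(trough) concentrations are observed, absorption is not identifiable and the
absorption rate constant is fixed at `ka = 1.9` per hour; bioavailability is
absorbed into apparent parameters, CL/F (L/h) and V/F (L). At steady state
the concentration `t` hours after a dose of `D` mg every `tau` hours is the
standard superposition closed form

$$C(t) = \frac{D\,k_a}{V/F\,(k_a-k_e)}\left[
\frac{e^{-k_e t}}{1-e^{-k_e\tau}} - \frac{e^{-k_a t}}{1-e^{-k_a\tau}}
\right],\qquad k_e = \frac{CL/F}{V/F},$$

with the analytic L'Hôpital limit substituted when `|ka - ke| / ka < 1e-9`
(the two-exponential form is numerically singular there; the switch
threshold is far below any parameter precision that matters).

Typical clearance carries the covariate model. In the final model,

$$CL/F = \theta_{CL}\cdot(\mathrm{AGE}/5)^{\theta_{age}}
\cdot \theta_{AG}^{[AG]}\cdot\theta_{GG}^{[GG]},$$

with `theta_CL = 0.214` L/h for a five-year-old *ABCB1* rs3789243 AA child,
age exponent `0.357`, and genotype multipliers `0.953` (AG) and `1.08`
(GG); `V/F = 3.63` L. The age term is centred at 5 years: at the near-median
reference age the typical clearance then coincides with the covariate-free
base-model value (0.205 L/h), which is how the centring was disambiguated;
the reference age is a constructor argument. Between-subject variability is
a single log-normal random effect on clearance, `CL_i = CL/F * exp(eta)`,
`eta ~ N(0, omega^2)`; variability on V/F is deliberately absent (with
trough-only data its estimate is hopelessly imprecise). Residual error is
additive with SD `sigma = 11.9` mg/L by default; proportional and combined
forms are available. The `omega` of 0.169 is interpreted as the standard
deviation of `eta` (an approximate 16.9% CV of clearance); read as a
variance it would imply an implausible 41% CV.

## Estimation

With one random effect per subject the marginal likelihood is a 1-D
integral, and the package computes it essentially exactly rather than by
linearization. For each subject the conditional mode of `eta` is found by a
vectorized damped Newton iteration (finite-difference derivatives, all
subjects updated simultaneously; a scalar golden-section fallback catches
the rare subject whose gradient has not vanished). Adaptive Gauss–Hermite
quadrature is then centred at the mode with curvature-matched scaling
(21 nodes by default; accuracy checks in the test suite compare 41-node
quadrature against dense trapezoid integration and require relative
agreement better than 1e-6). A FOCE-I-style engine — first-order
linearization of the prediction around the conditional mode with
interaction, evaluated through rank-1 Woodbury identities — is provided for
comparison with the classical approximation; on well-behaved data the two
agree within one OFV unit.

The OFV (`-2` log marginal likelihood) is minimized by `nlminb` over
log-transformed scale parameters (clearance, volume, multipliers, omega,
sigma) and untransformed covariate exponents, with generous physiological
box bounds (e.g. `V/F <= 1000` L). The bounds matter: once V/F grows large
the trough approaches its infusion limit `dose rate / CL` and the
likelihood becomes flat in V, so an unbounded search can drift arbitrarily
far along a ridge that the data cannot resolve. Relative convergence
tolerance is 1e-10 with up to 500 iterations; when `nlminb` reports "false
convergence" (typical when a bootstrap replicate is started at, and cannot
improve on, the reference optimum) the fit is accepted if the numerical
gradient vanishes. Standard errors come from the finite-difference Hessian
of OFV/2 in the natural parameterization; a singular or indefinite Hessian
yields missing RSEs, never an error. Empirical Bayes estimates are the
conditional modes; eta-shrinkage is `100(1 - SD(eta_hat)/omega)` and
epsilon-shrinkage `100(1 - SD(IWRES))`. CWRES decorrelate each subject's
residuals with the inverse square root of the FOCE-linearized marginal
covariance.

## Covariate search

`screen_candidates()` builds the candidate set: age, weight and daily dose
(mg/kg/day, derived as `DOSE_MG * 24 / II_H / WT` when absent) as
continuous covariates; sex; co-medications present on at least 2.5% of
sample rows (rarer flags carry no power); and every SNP column whose
subject-level genotype counts pass the Hardy–Weinberg chi-square screen at
`alpha = 0.05`. Genotypes enter as three-level categorical multipliers with
the major-allele homozygote as reference. Continuous forms are power,
linear, exponential or two-slope piecewise, all centred (age at 5 y, weight
at 20 kg, daily dose at its median); the linear and piecewise effects are
floored at 1e-3 so a trial coefficient cannot drive clearance negative.

Forward inclusion accepts the candidate with the largest OFV drop exceeding
`qchisq(0.95, df)` — 3.84 for one parameter, 5.99 when both genotype levels
enter jointly — with ties broken by lower AIC, then fewer parameters, then
name. Backward elimination uses the conventional stricter `qchisq(0.99,
df)` (6.63 for 1 df); the forward criterion alone is stated in the source
analysis, and the stricter backward cut does not change which terms survive
(the retained effects sit far above either threshold). A term eliminated
backwards is not re-offered, which guarantees termination. The full
hypothesis-testing trace (every candidate, form, OFV pair and decision) is
returned as a data frame.

## Evaluation

The bootstrap resamples *subjects* with replacement (preserving
within-subject correlation — the natural unit for hierarchical data),
refits from the reference estimates, and requires optimizer success plus a
positive-definite Hessian for a replicate to count; medians, 2.5/97.5
percentiles and the relative error `100 (median - reference)/reference` are
reported over successes. The VPC re-simulates the original design with
fresh random effects and residual noise and overlays observed 5th/50th/95th
percentiles on the simulation band. Because every sample is a trough, the
time axis is nearly degenerate; binning by age (the model's main covariate
axis) is the default, time binning remains available. Bins with fewer than
five observations are merged. Full-scale analyses use 1,000 bootstrap runs
and 1,000 VPC simulations; the test suite runs 100 and 200 respectively,
which is ample for the self-consistency properties it asserts.

## Dose simulation

`simulate_pta()` draws virtual children uniformly in age within a subgroup
bin, assigns weight by the standard pediatric rule `weight = 2(age + 4)` kg
clamped to 10–40 kg, fixes the genotype, draws fresh `eta`, and computes
the steady-state trough of a twice-daily regimen delivering a given
mg/kg/day. PTA is the percentage of troughs inside 50–100 mg/L, with 70%
the adequacy bar. Residual (assay) error is excluded by default — PTA is
about true exposure, not measurement replication — and can be switched on.
`recommend_dose()` implements both the minimal-adequate-dose rule and a
max-PTA rule; the two differ exactly where the source analysis recommends a
higher dose (GG toddlers) than the minimal rule would.

One structural property deserves honesty: under the fitted covariate model,
clearance grows as `age^0.357` while any realistic weight-for-age curve
grows more slowly below about three years, so *per-kilogram* clearance
peaks in toddlers and the deterministic trough at fixed mg/kg/day dips
between the 1–2 y and 3–4 y bins (39.7, 37.3, 36.9, 37.3, 38.6, 40.1,
41.6 mg/L at 15 mg/kg/day across the seven default bins). Attainment
orderings across age are therefore monotone only from the 3–4 y bin
upward, and the package's tests assert exactly that; a strictly monotone
pattern across all bins would require toddler weight growth of roughly 26%
per year, about double physiological reality, and cannot be produced by
this model under any defensible weight mapping.

For the trough-versus-weight profile the virtual patient is a *typical*
child: age (hence clearance) is held at the reference value and weight only
scales the absolute dose, so the mean trough rises strictly with weight and
crosses the 100 mg/L toxicity bound above 20 kg at 40 mg/kg/day. Coupling
age to weight through the inverse weight rule is available
(`age_from_weight = TRUE`) but is not the default precisely because the
coupling reintroduces the toddler dip and contradicts the monotone
weight-exposure relationship the profile is meant to display.

## The synthetic cohort

`generate_cohort()` emulates the study population so that every stage is
testable without patient data: 103 subjects contributing 2–5 troughs each
(mean ≈ 3.65, hence ≈ 376 observations); ages from a truncated log-normal
solved numerically to hit mean 5.30 y and SD 3.39 y on [0.5, 15] (the
stated minimum forces right skew, so a truncated normal would be wrong);
weights from the pediatric rule times log-normal noise (15% CV), clipped to
[6.5, 52] kg; daily doses from a truncated normal (23.8 ± 5.7, range
9.9–45.7 mg/kg/day) rounded to practical 5 mg administrations; genotypes
for all fifteen panel SNPs drawn under Hardy–Weinberg proportions at the
observed allele frequencies; co-medication flags at the observed sample
proportions; and observations generated from the final model with additive
noise, redrawing (and counting) any value under the 1 mg/L quantification
limit.

Sixty percent of virtual subjects take the drug every 12 h and forty
percent every 8 h, mirroring the two-to-three-times-daily regimens of the
source cohort. This mix is also load-bearing for identifiability: with a
single interval and a single sampling time, (CL/F, V/F) lie on a nearly
flat likelihood ridge and the ML estimate can land far from the generating
values; two intervals anchor the accumulation ratio and restore the
moderate precision on V/F that the original analysis reports (23.8% RSE).

What the generator does *not* emulate: longitudinal growth within subject,
pharmacokinetic interactions of co-medications (none survived selection in
the source analysis), saturable protein binding (the model is linear in
dose by construction), or assay censoring below the quantification limit
(values are redrawn rather than censored, keeping the design balanced — the
event has negligible probability under the default parameters anyway).
Passing tests therefore demonstrate internal consistency of the method
under the stated generative assumptions, not robustness to the messiness of
real TDM data.

## Problem sizes and reproducibility

All stochastic functions take explicit seeds; no hidden RNG state is used.
The test suite exercises: exact worked examples and closed-form limits;
quadrature against brute-force integration (5 subjects, 1e5 grid points);
simulation-reestimation over 10 replicate cohorts of the full study size
(medians of all recovered parameters within 10%, volume within 30%,
matching its weak identifiability); stepwise operating characteristics over
20 null and 20 age-effect replicates plus collinearity behaviour on 5;
a 100-run bootstrap and 200-replicate VPC; and PTA grids at n = 10,000 per
cell. These sizes were chosen so the whole suite completes in well under
half an hour on a single core while keeping every Monte Carlo assertion
comfortably clear of its own sampling error.
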