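#' Steady-state concentration for repeated oral dosing
#'
#' Closed-form concentration of a one-compartment model with first-order
#' absorption and elimination under repeated dosing of `dose` mg every
#' `tau` hours, evaluated at `t` hours after a dose at steady state:
#'
#' \deqn{C(t) = \frac{D k_a}{V (k_a - k_e)}
#'   \left[\frac{e^{-k_e t}}{1 - e^{-k_e \tau}}
#'       - \frac{e^{-k_a t}}{1 - e^{-k_a \tau}}\right]}
#'
#' with `ke = cl / v`. All arguments are vectorized. When `ka` and `ke`
#' coincide to within a relative 1e-9 the analytic limit
#' \eqn{C(t) = \frac{D k}{V} e^{-k t}\left[\frac{t}{1 - e^{-k\tau}} +
#' \frac{\tau e^{-k\tau}}{(1 - e^{-k\tau})^2}\right]} is used instead of the
#' (numerically singular) standard form.
#'
#' @param dose dose per administration (mg), `>= 0`.
#' @param tau dosing interval (h), `> 0`.
#' @param t time after the last dose (h), in `(0, tau]`.
#' @param cl apparent clearance CL/F (L/h).
#' @param v apparent volume V/F (L).
#' @param ka absorption rate constant (1/h).
#' @return Concentration (mg/L); linear in `dose`.
#' @examples
#' # trough of a 250 mg q12h regimen at the typical final-model parameters
#' steady_state_conc(250, 12, 12, cl = 0.214, v = 3.63, ka = 1.9)  # ~69.1
#' @export
steady_state_conc <- function(dose, tau, t, cl, v, ka) {
  stopifnot(all(dose >= 0), all(tau > 0), all(cl > 0), all(v > 0),
            all(ka > 0))
  if (any(t <= 0) || any(t > tau)) {
    stop("time after dose must lie in (0, tau]")
  }
  conc_ss_(dose, tau, t, cl, v, ka)
}

# Internal unchecked vectorized kernel (hot path of the likelihood).
conc_ss_ <- function(dose, tau, t, cl, v, ka) {
  ke <- cl / v
  eket <- exp(-ke * t)
  eketau <- exp(-ke * tau)
  ekat <- exp(-ka * t)
  ekatau <- exp(-ka * tau)
  conc <- dose * ka / (v * (ka - ke)) *
    (eket / (1 - eketau) - ekat / (1 - ekatau))
  near <- abs(ka - ke) < 1e-9 * ka
  if (any(near)) {
    # L'Hopital limit as ke -> ka (absorption and elimination equal)
    k <- ke[near] * rep_len(1, sum(near))
    tt <- rep_len(t, length(ke))[near]
    tautau <- rep_len(tau, length(ke))[near]
    dd <- rep_len(dose, length(ke))[near]
    vv <- rep_len(v, length(ke))[near]
    e <- exp(-k * tautau)
    conc[near] <- dd * k / vv * exp(-k * tt) *
      (tt / (1 - e) + tautau * e / (1 - e)^2)
  }
  conc
}

#' Predicted steady-state trough for subjects in a dataset
#'
#' Composes the covariate model ([typical_clearance()]), the
#' inter-individual model ([individual_clearance()]) and the steady-state
#' solution ([steady_state_conc()]): the prediction for each row is the
#' concentration at `TIME_H` after a dose of `DOSE_MG` every `II_H` hours.
#' With `eta = 0` this is the population prediction (PRED); with a subject's
#' empirical Bayes estimate it is the individual prediction (IPRED).
#'
#' @param model a [vpa_model()].
#' @param data data frame with the covariate columns used by the model plus
#'   `DOSE_MG`, `II_H` and `TIME_H`.
#' @param eta random effect, a scalar or one value per row.
#' @return Predicted concentration (mg/L) per row.
#' @export
predict_trough <- function(model, data, eta = 0) {
  stopifnot(inherits(model, "vpa_model"))
  need <- c("DOSE_MG", "II_H", "TIME_H")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing dosing columns: ",
                         paste(miss, collapse = ", "))
  cl <- individual_clearance(typical_clearance(model, data), eta)
  steady_state_conc(data$DOSE_MG, data$II_H, data$TIME_H,
                    cl, model$theta_v, model$ka)
}
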