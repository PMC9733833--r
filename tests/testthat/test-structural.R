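test_that("typical clearance reproduces the covariate equation", {
  m <- vpa_final_model()
  # reference child: 5 years, AA -> theta_cl exactly
  expect_equal(typical_clearance(m, data.frame(AGE = 5, rs3789243 = "AA")),
               0.214, tolerance = 1e-12)
  # genotype multipliers are plain products
  expect_equal(typical_clearance(m, data.frame(AGE = 5, rs3789243 = "GG")),
               0.214 * 1.08, tolerance = 1e-12)
  expect_equal(typical_clearance(m, data.frame(AGE = 1.25,
                                               rs3789243 = "AG")),
               0.214 * 0.25^0.357 * 0.953, tolerance = 1e-10)
  # vectorized over rows
  cl <- typical_clearance(m, data.frame(AGE = c(5, 5, 1.25),
                                        rs3789243 = c("AA", "GG", "AG")))
  expect_equal(cl[2] / cl[1], 1.08)
  expect_error(
    typical_clearance(m, data.frame(AGE = 5, rs3789243 = "GA")),
    "GA.*rs3789243|rs3789243.*GA")
})

test_that("individual clearance is log-normal in eta", {
  expect_identical(individual_clearance(0.214, 0), 0.214)
  expect_equal(individual_clearance(0.214, log(2)), 0.428)
  expect_equal(individual_clearance(0.1, -0.169), 0.1 * exp(-0.169))
  # monotone increasing in eta
  etas <- seq(-1, 1, by = 0.1)
  expect_true(all(diff(individual_clearance(0.2, etas)) > 0))
})

test_that("steady-state closed form agrees with dose superposition", {
  # enough single doses that the omitted tail is < 1e-6 of the total
  oracle <- superposition_trough(250, 12, 12, cl = 0.214, v = 3.63,
                                 ka = 1.9, n_doses = 400)
  closed <- steady_state_conc(250, 12, 12, cl = 0.214, v = 3.63, ka = 1.9)
  expect_lt(abs(closed - oracle), 0.01)
  expect_equal(closed, 69.087, tolerance = 1e-4)
  # other corners of the (cl, v, tau) space
  for (prm in list(c(0.1, 2, 8), c(0.5, 6, 24), c(0.05, 1.2, 12))) {
    o <- superposition_trough(100, prm[3], prm[3] / 2, prm[1], prm[2],
                              1.9, n_doses = 600)
    c2 <- steady_state_conc(100, prm[3], prm[3] / 2, prm[1], prm[2], 1.9)
    expect_equal(c2, o, tolerance = 1e-3)
  }
})

test_that("concentration is linear in dose and zero at zero dose", {
  t <- c(2, 6, 12)
  c1 <- steady_state_conc(125, 12, t, 0.2, 3.5, 1.9)
  c2 <- steady_state_conc(250, 12, t, 0.2, 3.5, 1.9)
  expect_equal(c2, 2 * c1, tolerance = 1e-14)
  expect_identical(steady_state_conc(0, 12, 12, 0.2, 3.5, 1.9), 0)
  expect_true(all(c1 > 0))
})

test_that("trough decreases with clearance, and splitting the daily dose raises the trough", {
  cls <- seq(0.05, 0.6, by = 0.05)
  troughs <- steady_state_conc(250, 12, 12, cls, 3.63, 1.9)
  expect_true(all(diff(troughs) < 0))
  # same mg/day: q12h trough above q24h trough
  q12 <- steady_state_conc(250, 12, 12, 0.214, 3.63, 1.9)
  q24 <- steady_state_conc(500, 24, 24, 0.214, 3.63, 1.9)
  expect_gt(q12, q24)
})

test_that("absorption-elimination degeneracy uses the analytic limit", {
  v <- 3.63
  ka <- 1.9
  cl_eq <- ka * v  # ke == ka exactly
  lim <- steady_state_conc(250, 12, 6, cl_eq, v, ka)
  expect_true(is.finite(lim) && lim > 0)
  # continuous across the switch
  near <- steady_state_conc(250, 12, 6, cl_eq * (1 + 1e-7), v, ka)
  expect_equal(near, lim, tolerance = 1e-4)
  expect_error(steady_state_conc(250, 12, 0, 0.2, v, ka), "time after dose")
  expect_error(steady_state_conc(250, 12, 13, 0.2, v, ka),
               "time after dose")
})

test_that("final-model half-life lies in the reported pediatric range", {
  m <- vpa_final_model()
  t_half <- log(2) * m$theta_v / m$theta_cl
  expect_gte(t_half, 10)
  expect_lte(t_half, 13)
})

test_that("predict_trough composes clearance, random effect and the steady state", {
  m <- vpa_final_model()
  row <- data.frame(AGE = 5, rs3789243 = "AA", DOSE_MG = 250, II_H = 12,
                    TIME_H = 12)
  expect_equal(predict_trough(m, row, eta = 0),
               steady_state_conc(250, 12, 12, 0.214, 3.63, 1.9))
  # higher clearance (eta) -> lower trough
  tr <- vapply(seq(-0.5, 0.5, by = 0.1),
               function(e) predict_trough(m, row, eta = e), 0)
  expect_true(all(diff(tr) < 0))
})
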