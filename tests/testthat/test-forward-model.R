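test_that("compiled and pure-R derivatives agree", {
  p <- model_params(phi = 0.3)
  set.seed(4)
  for (i in 1:5) {
    y <- batch_state(A = runif(1, 0.5, 3), B = runif(1, 0.5, 2.5),
                     C = runif(1, 0.01, 0.5),
                     d15_A = runif(1, -10, 40), d15_B = runif(1, -10, 40),
                     d15_C = runif(1, -10, 40),
                     d18_B = runif(1, -10, 60), d18_C = runif(1, -10, 60))
    dR <- derivatives(y, p)
    out <- deSolve::lsoda(unname(y), c(0, 1e-9), func = "amx_derivs",
                          parms = anammoxiso:::.parms_vector(p),
                          dllname = "anammoxiso", initfunc = "amx_initmod")
    dC <- (out[2, -1] - out[1, -1]) / 1e-9
    expect_equal(unname(dR), unname(dC), tolerance = 1e-5)
  }
})

test_that("no fractionation and no exchange leaves all deltas constant", {
  p <- model_params(e15_AMO = 0, e15_NIR = 0, e15_NXR = 0,
                    e18_NIR = 0, e18_NXR = 0, e18_H2O = 0,
                    k_eq_abio = 0, k_eq_AMX = 0, e18_eq = 0, d18_H2O = 12)
  init <- batch_state(2.5, 2, 0.05, d15_A = 5, d15_B = 5, d15_C = 5,
                      d18_B = 12, d18_C = 12)
  tr <- simulate_batch(p, init, seq(0, 5, 0.5))
  expect_gt(max(abs(diff(tr$conc_NO2))), 0)  # concentrations still evolve
  for (v in c("d15N_NH4", "d15N_NO2", "d15N_NO3", "d18O_NO2", "d18O_NO3"))
    expect_lt(max(abs(tr[[v]] - tr[[v]][1])), 1e-7)
})

test_that("single-sink runs follow closed-system Rayleigh systematics", {
  p <- model_params(F_AMO = 0.24, F_NIR = 0.33, F_NXR = 0,
                    k_eq_abio = 0, k_eq_AMX = 0)
  tr <- simulate_batch(p, batch_state(d15_B = 3), seq(0, 5.8, 0.2))
  f <- tr$conc_NO2 / tr$conc_NO2[1]
  expected <- rayleigh_delta(f, 3, p$e15_NIR)
  expect_lt(max(abs(tr$d15N_NO2 - expected)), 0.1)
})

test_that("exchange-only runs relax exponentially at k_abio + k_AMX", {
  p <- model_params(F_AMO = 0, F_NIR = 0, F_NXR = 0,
                    k_eq_AMX = 0.1356, k_eq_abio = 0.0113, d18_H2O = 110.1)
  init <- batch_state(2.5, 2, 0.02, d18_B = 0, d18_C = 15)
  t <- seq(0, 20, 0.5)
  tr <- simulate_batch(p, init, t, rtol = 1e-12, atol = 1e-16)
  # exact linear relaxation in atom-fraction space, rate 0.1469 / h
  y <- delta_to_fraction(tr$d18O_NO2, R18_VSMOW)
  y_eq <- ratio_to_fraction(alpha_of(11.9) * delta_to_ratio(110.1, R18_VSMOW))
  y_expect <- y_eq + (y[1] - y_eq) * exp(-0.1469 * t)
  expect_lt(max(abs(y - y_expect) / abs(y[1] - y_eq)), 1e-8)
  # e-folding time 6.81 h: closed form in atom-fraction space
  y0f <- delta_to_fraction(0, R18_VSMOW)
  y1 <- y_eq + (y0f - y_eq) * exp(-1)
  expect_equal(relax(0, 1 / 0.1469, 0.1469, 110.1),
               fraction_to_delta(y1, R18_VSMOW), tolerance = 1e-9)
})

test_that("nitrogen and oxygen pools are conserved including backflux", {
  for (phi in c(0, 0.5, 0.75)) {
    p <- model_params(d18_H2O = 56.7, phi = phi)
    tr <- simulate_batch(p, batch_state(2.5, 2, 0.02, 0, 0, 20, 0, 15),
                         seq(0, 5, 0.5))
    st <- attr(tr, "state")
    n_tot <- st[, 2] + st[, 3] + st[, 4] + st[, 10]
    n15 <- st[, 5] + st[, 6] + st[, 7] + st[, 11]
    o18 <- st[, 8] + st[, 9] + st[, 12] + st[, 15] - st[, 13] - st[, 14]
    expect_lt(max(abs(n_tot - n_tot[1])) / n_tot[1], 1e-8)
    expect_lt(max(abs(n15 - n15[1])) / n15[1], 1e-8)
    expect_lt(max(abs(o18 - o18[1])) / o18[1], 1e-8)
  }
})

test_that("trajectory invariants hold and residual deltas grow monotonically", {
  p <- model_params(k_eq_abio = 0, k_eq_AMX = 0)
  tr <- simulate_batch(p, batch_state(), seq(0, 5.9, 0.25))
  expect_true(all(diff(tr$conc_NO2) <= 1e-12))
  expect_true(all(diff(tr$conc_NO3) >= -1e-12))
  expect_true(all(diff(tr$time_h) > 0))
  # normal effects, no exchange: residual-pool deltas non-decreasing
  expect_true(all(diff(tr$d15N_NH4) >= -1e-9))
  expect_true(all(diff(tr$d15N_NO2) >= -1e-9))
})

test_that("the adaptive solver matches the step-halving Euler oracle", {
  p <- model_params(d18_H2O = 110.1)
  y0 <- batch_state(2.5, 2, 0.02, 0, 0, 20, 0, 15)
  eo <- euler_oracle(p, y0, t_end = 5.5, dt = 1e-3)
  tr <- simulate_batch(p, y0, c(0, 5.5), rtol = 1e-11, atol = 1e-13)
  ad <- attr(tr, "state")[2, -1]
  expect_lt(max(abs(eo - ad)), 1e-6)
})

test_that("nitrite exhaustion is detected and the state frozen after it", {
  p <- model_params(d18_H2O = 110.1)
  tr <- simulate_batch(p, batch_state(), seq(0, 8, 0.25))
  tex <- attr(tr, "diagnostics")$t_exhaust
  expect_gt(tex, 5); expect_lt(tex, 7)
  after <- tr[tr$time_h > tex + 0.1, ]
  expect_lt(max(abs(diff(after$conc_NH4))), 1e-10)
  expect_lt(min(after$conc_NO2), 1e-8)
})

test_that("anammox-mediated exchange drives NO2- d18O near equilibrium where abiotic exchange cannot", {
  d_eq <- equilibrium_delta(110.1)
  p_amx <- model_params(d18_H2O = 110.1)
  p_abio <- model_params(d18_H2O = 110.1, k_eq_AMX = 0)
  t <- seq(0, 6, 0.1)
  fin <- function(p) {
    tr <- simulate_batch(p, batch_state(), t)
    tr$d18O_NO2[nrow(tr)]
  }
  expect_lt(abs(fin(p_amx) - d_eq), 20)
  expect_gt(abs(fin(p_abio) - d_eq), 60)
})

test_that("instantaneous nitrate production is isotopically heavier than nitrite", {
  # inverse effect of nitrite oxidation: the first produced NO3- exceeds
  # the current NO2- d15N by about |e15_NXR|
  p <- model_params()
  tr <- simulate_batch(p, batch_state(C = 1e-6), seq(0, 0.2, 0.01))
  d_prod <- delta15N_produced(tr$conc_NO3[1], tr$d15N_NO3[1],
                              tr$conc_NO3[5], tr$d15N_NO3[5])
  expect_gt(d_prod - tr$d15N_NO2[1], 15)
  expect_lt(d_prod - tr$d15N_NO2[1], 20)
})

test_that("fluxes_from_stoichiometry maps consumption ratios to branch fluxes", {
  f <- fluxes_from_stoichiometry(0.4, 1.38, 0.33)
  expect_equal(f$F_NXR, 0.132)
  expect_equal(f$F_NIR, 0.42)
  f2 <- fluxes_from_stoichiometry(0.4, 1.146, 0.161)
  expect_equal(f2$F_NXR, 0.0644)
  expect_equal(f2$F_NIR, 0.394)
  f3 <- fluxes_from_stoichiometry(0.4, 1.38, 0)
  expect_equal(f3$F_NXR, 0)
  expect_equal(f3$F_NIR, 1.38 * 0.4)
  expect_error(fluxes_from_stoichiometry(0.4, 0.3, 0.33), "dNO2_dNH4 > dNO3_dNH4")
})

test_that("exact and delta-linear model variants agree at study conditions", {
  p <- model_params()
  y0 <- batch_state(2.5, 2, 0.02, 0, 0, 20, 0, 15)
  t <- seq(0, 5.5, 0.25)
  a <- simulate_batch(p, y0, t)
  b <- simulate_batch_linear(p, y0, t)
  for (v in c("d15N_NH4", "d15N_NO2", "d15N_NO3", "d18O_NO2", "d18O_NO3"))
    expect_lt(max(abs(a[[v]] - b[[v]])), 0.5)
})
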