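test_that("produced-nitrate d15N follows the mass-balance difference formula", {
  expect_equal(delta15N_produced(1, 100, 2, 60), 20)
  expect_equal(delta15N_produced(1, 50, 3, 50), 50)   # production at pool composition
  expect_equal(delta15N_produced(0, 0, 1.5, 37), 37)  # all product is new
  expect_error(delta15N_produced(2, 10, 2, 10), "Ct > C0")
  expect_error(delta15N_produced(-1, 10, 2, 10), ">= 0")
})

test_that("delta15N_produced applied to model output returns the flux-weighted product", {
  p <- model_params()
  tr <- simulate_batch(p, batch_state(C = 0.02, d15_C = 20), seq(0, 5, 0.25))
  prod <- delta15N_produced(tr$conc_NO3[1], tr$d15N_NO3[1],
                            tr$conc_NO3[-1], tr$d15N_NO3[-1])
  # cumulative produced NO3- is heavier than coexisting NO2- (inverse effect)
  expect_true(all(prod[-1] > tr$d15N_NO2[-c(1, 2)]))
  # and bounded by the instantaneous product at the extremes of the run
  inst0 <- ratio_to_delta(apply_kinetic_effect(
    delta_to_ratio(tr$d15N_NO2[1], R15_AIR), p$e15_NXR), R15_AIR)
  expect_equal(prod[1], inst0, tolerance = 0.5)
})

test_that("two-pool mixing is exact amount-weighted mass balance", {
  m <- mix_pools(0.02, 800, 20, 5, 8, 180)
  expect_equal(m$conc, 56 / 808)
  expect_equal(m$delta, 134.3, tolerance = 0.1)
  expect_equal(mix_pools(1, 10, 42, 1, 90, 42)$delta, 42, tolerance = 1e-10)
  expect_equal(mix_pools(0.5, 100, 7, 3, 0, 99), list(conc = 0.5, delta = 7))
  expect_error(mix_pools(0, 10, 5, 0, 10, 5), "total amount")
})

test_that("combined oxygen effect is the 2:1 atom-weighted sum", {
  expect_equal(combined_o_effect(-2.9, 19.2), 2 / 3 * -2.9 + 1 / 3 * 19.2)
  expect_equal(combined_o_effect(-2.9, 19.2), 4.47, tolerance = 0.01)
  expect_equal(combined_o_effect(-11.0, 16.4), -1.87, tolerance = 0.01)
  expect_equal(combined_o_effect(0, 0), 0)
})

test_that("the dual-isotope nitrate trajectory stays below 0.3 under full equilibrium", {
  ex <- trajectory_exercise(times = seq(0, 5.8, length.out = 25))
  expect_lt(ex$max_ratio, 0.3)
  expect_equal(sort(unique(ex$curves$d18_H2O)), seq(-7.7, 1.8, length.out = 5))
  # robustness: the headline bound is invariant to the Dd15N floor in [0.5, 2]
  for (fl in c(0.5, 2)) {
    exf <- trajectory_exercise(times = seq(0, 5.8, length.out = 25), floor = fl)
    expect_lt(exf$max_ratio, 0.3)
  }
})

test_that("a construction with mirrored N and O bookkeeping gives ratio ~ 1", {
  p <- model_params(e15_AMO = 30, e15_NIR = 0, e15_NXR = 0,
                    e18_NXR = 0, e18_H2O = 0, e18_eq = 0, d18_H2O = 0)
  init <- batch_state(2.5, 2, 0.02, d15_B = 0, d15_C = -10,
                      d18_B = 0, d18_C = -10)
  ex <- trajectory_exercise(p, d18_grid = 0, times = seq(0, 5.5, 0.25),
                            init = init)
  ok <- !is.na(ex$curves$ratio)
  expect_true(any(ok))
  expect_equal(ex$curves$ratio[ok], rep(1, sum(ok)), tolerance = 1e-3)
})

test_that("pinned-equilibrium trajectories agree with the Euler oracle", {
  p <- pooled_reference_params(d18_H2O = -7.7)
  pin <- equilibrium_delta(-7.7, p$e18_eq)
  init <- batch_state(2.5, 2, 0.02, d15_C = 20, d18_B = pin, d18_C = 15)
  eo <- euler_oracle(p, init, t_end = 4, dt = 1e-3, pin_d18_NO2 = pin)
  tr <- simulate_batch(p, init, c(0, 4), pin_d18_NO2 = pin,
                       rtol = 1e-11, atol = 1e-13)
  ad <- attr(tr, "state")[2, -1]
  ratio_of <- function(y) {
    y <- unname(y)  # state positions: C = 3, C15 = 6, C18 = 8
    d15 <- fraction_to_delta(y[6] / y[3], R15_AIR)
    d18 <- fraction_to_delta(y[8] / (3 * y[3]), R18_VSMOW)
    (d18 - 15) / (d15 - 20)
  }
  expect_equal(ratio_of(eo), ratio_of(ad), tolerance = 1e-4)
})

test_that("no backward flux up to 75% reaches exchange equilibrium by exhaustion", {
  bf <- backflux_exercise()
  expect_equal(bf$phi, c(0, 0.25, 0.5, 0.75))
  # offsets far above analytical precision (0.3 permil) for every phi
  expect_true(all(bf$offset > 10 * 0.3))
  # more back-mixing moves NO2- towards the water/nitrate signature
  expect_true(all(diff(bf$offset) < 0))
  # phi = 0 is the pure abiotic-exchange limit of the same run
  p0 <- pooled_reference_params(k_eq_AMX = 0, d18_H2O = 110.1)
  tr <- simulate_batch(p0, batch_state(A = 2.5, B = 2, C = 1e-3,
                                       d15_C = 20, d18_C = 15),
                       seq(0, 0.995 * 2 / (p0$F_NIR + p0$F_NXR), length.out = 30))
  expect_equal(bf$final_d18O_NO2[1], tr$d18O_NO2[nrow(tr)], tolerance = 1e-6)
})
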