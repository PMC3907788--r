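test_that("steady-state evaluation matches its closed form and saturates", {
  sch <- gating_scheme("activation", vh = -40, k = 6, tau_min = 1)
  expect_equal(evaluate_steady_state(sch, -40), 0.5)
  expect_lt(abs(evaluate_steady_state(sch, 200) - 1), 1e-6)
  # independent re-evaluation of the same closed form
  v <- c(-80, -60, -40, -20, 0)
  expect_equal(evaluate_steady_state(sch, v),
               1 / (1 + exp(-(v - (-40)) / 6)), tolerance = 1e-12)
  expect_error(evaluate_steady_state(sch, NaN), "finite")
})

test_that("gate advance is the exact exponential update", {
  sch <- gating_scheme("activation", vh = -35, k = 7, tau_min = 2,
                       tau_amp = 8, vt = -35)
  expect_equal(advance_gate(sch, 0.3, -50, 0), 0.3)
  expect_lt(abs(advance_gate(sch, 0.3, -50, 1e6) -
                  evaluate_steady_state(sch, -50)), 1e-9)
  expect_error(advance_gate(sch, 0.3, -50, -1), "non-negative")

  # fine-step iteration vs high-accuracy ODE integration of dx/dt=(xinf-x)/tau
  v <- -48
  x <- 0.1
  for (i in 1:400) x <- advance_gate(sch, x, v, 0.025)
  sol <- deSolve::ode(
    y = c(x = 0.1), times = c(0, 10),
    func = function(t, y, p) {
      list((sch$steady_state_fn(v) - y) / sch$time_constant_fn(v))
    }, rtol = 1e-10, atol = 1e-12)
  expect_lt(abs(x - sol[2, "x"]), 1e-6)
})

test_that("gate advance has the semigroup property", {
  sch <- gating_scheme("inactivation", vh = -60, k = -6, tau_min = 3,
                       tau_amp = 10, vt = -55)
  for (v in c(-80, -60, -40)) {
    one <- advance_gate(sch, 0.7, v, 0.5)
    two <- advance_gate(sch, advance_gate(sch, 0.7, v, 0.25), v, 0.25)
    expect_lt(abs(one - two), 1e-12)
  }
})

test_that("gate trajectories stay within [0,1] under random voltage steps", {
  set.seed(11)
  sch <- gating_scheme("activation", vh = -30, k = 5, tau_min = 0.5,
                       tau_amp = 5, vt = -40)
  for (rep in 1:5) {
    x <- runif(1)
    for (i in 1:200) {
      x <- advance_gate(sch, x, runif(1, -120, 60), runif(1, 0, 2))
      expect_true(x >= 0 && x <= 1)
    }
  }
})

test_that("channel current follows the ohmic form", {
  gates <- list(gating_scheme("activation", vh = -35, k = 6, exponent = 3L),
                gating_scheme("inactivation", vh = -60, k = -6))
  na <- channel_spec("Na", gbar = 0.135, reversal = 55, gates = gates)
  expect_equal(channel_current(na, c(0.4, 0.6), v = 55), 0)
  expect_equal(channel_current(na, c(0, 0), v = -20), 0)
  # published FS somatic density, all gates open, 10 mV driving force
  na2 <- channel_spec("Na", gbar = 0.135, reversal = 55,
                      gates = list(gates[[1]]))
  expect_equal(channel_current(na2, 1, v = 65), 1.35)
  # linear in gbar and driving force
  half <- channel_spec("Na", gbar = 0.135 / 2, reversal = 55,
                       gates = list(gates[[1]]))
  expect_equal(channel_current(half, 0.5, v = 65) * 2,
               channel_current(na2, 0.5, v = 65))
  expect_equal(channel_current(na2, 0.5, v = 75),
               2 * channel_current(na2, 0.5, v = 65))
  expect_error(channel_current(na, c(0.5), v = 0), "gate values")
})

test_that("calcium pool relaxes correctly", {
  pool <- calcium_pool(concentration = 2e-4, rest_concentration = 5e-5,
                       decay_tau = 50, influx_factor = 5e-3)
  expect_equal(advance_calcium(calcium_pool(), 0, 10)$concentration, 5e-5)
  # e-fold decay of the excess over one time constant
  adv <- advance_calcium(pool, 0, 50)
  expect_lt(abs((adv$concentration - 5e-5) - (2e-4 - 5e-5) * exp(-1)), 1e-9)
  # closed-form fixed point under constant inward current
  p <- calcium_pool()
  for (i in 1:2000) p <- advance_calcium(p, -0.05, 5)
  expect_equal(p$concentration, 5e-5 + 5e-3 * 0.05 * 50, tolerance = 1e-6)
  # monotone relaxation to rest with zero current
  p <- calcium_pool(concentration = 1e-3)
  prev <- p$concentration
  for (i in 1:20) {
    p <- advance_calcium(p, 0, 10)
    expect_lte(p$concentration, prev)
    expect_gte(p$concentration, p$rest_concentration)
    prev <- p$concentration
  }
})
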