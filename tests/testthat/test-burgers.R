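test_that("creep compliance has the correct limits and frozen mid-curve value", {
  p <- fix_liquid()
  # instantaneous elastic jump at force onset
  expect_identical(burgers_creep_compliance(p, 0), p$J1)
  # value at t = 10 s, frozen from independent ODE integration of the
  # spring-dashpot network (helper ode_burgers_response)
  expect_equal(burgers_creep_compliance(p, 10), 0.1996631027, tolerance = 1e-9)
  # solid limit: no flow term, J saturates at Je0
  solid <- burgers_params(0.1, 0.05, 2, Inf)
  expect_equal(burgers_creep_compliance(solid, 1e9), 0.15, tolerance = 1e-12)
  expect_error(burgers_creep_compliance(p, -1), "t must be")
})

test_that("compliance curve is nondecreasing with nonpositive curvature", {
  set.seed(42)
  for (i in 1:20) {
    p <- burgers_params(10^runif(1, -2, 1), 10^runif(1, -2, 1),
                        10^runif(1, -1, 1), 10^runif(1, 1, 4))
    t <- seq(0, 60, by = 0.1)
    J <- burgers_creep_compliance(p, t)
    expect_true(all(diff(J) >= -1e-14))
    expect_true(all(diff(diff(J)) <= 1e-12))
  }
})

test_that("long-time slope of J(t) equals 1/eta0", {
  set.seed(7)
  for (i in 1:10) {
    p <- burgers_params(10^runif(1, -2, 0), 10^runif(1, -2, 0),
                        10^runif(1, -1, 0.7), 10^runif(1, 1, 3))
    t <- seq(50 * p$tau, 100 * p$tau, length.out = 200)
    slope <- unname(coef(lm(burgers_creep_compliance(p, t) ~ t))[2])
    expect_equal(slope, 1 / p$eta0, tolerance = 1e-6)
  }
})

test_that("steady-state compliance is the flow-asymptote intercept", {
  p <- fix_liquid()
  expect_equal(steady_state_compliance(p), 0.15)
  expect_equal(steady_state_compliance(burgers_params(0.1, 0, 2, 200)), 0.1)
  # intercept of a straight-line fit to J(t) for t >= 20 tau (linear regime)
  t <- seq(20 * p$tau, 100 * p$tau, by = 0.5)
  icpt <- unname(coef(lm(burgers_creep_compliance(p, t) ~ t))[1])
  expect_equal(icpt, steady_state_compliance(p), tolerance = 1e-9)
})

test_that("parameter validation rejects unphysical materials", {
  expect_error(burgers_params(-0.1, 0.05, 2, 200), "J1")
  expect_error(burgers_params(0.1, -0.05, 2, 200), "J2")
  expect_error(burgers_params(0.1, 0.05, 0, 200), "tau")
  expect_error(burgers_params(0.1, 0.05, 2, -5), "eta0")
  # a solid (eta0 = Inf) is a valid material
  expect_s3_class(burgers_params(0.1, 0.05, 2, Inf), "burgers_params")
})

test_that("displacement response matches the ODE network oracle", {
  p <- fix_liquid()
  geom <- fix_geom()
  prot <- fix_protocol()
  tr <- burgers_displacement_response(p, geom$C, prot)
  J_closed <- tr$displacement_m * geom$C / prot$F0
  J_ode <- ode_burgers_response(p, tr$time_s,
                                step_times = c(0, 10, 30, 40),
                                step_signs = c(1, -1, 1, -1))
  expect_lt(max(abs(J_closed - J_ode) / pmax(abs(J_ode), 1e-12)), 1e-9)
})

test_that("recovery residual equals accumulated flow, zero for a solid", {
  geom <- fix_geom()
  # one long off phase so the retarded element fully relaxes
  prot <- force_protocol(F0 = 110e-9, t_on = 10, t_off = 200, n_cycles = 1)
  p <- fix_liquid()
  tr <- burgers_displacement_response(p, geom$C, prot)
  resid_J <- tr$displacement_m[nrow(tr)] * geom$C / prot$F0
  expect_equal(resid_J, 10 / 200, tolerance = 1e-6)
  # viscoelastic solid: complete recoil
  solid <- burgers_params(0.1, 0.05, 2, Inf)
  trs <- burgers_displacement_response(solid, geom$C, prot)
  expect_lt(abs(trs$displacement_m[nrow(trs)]) * geom$C / prot$F0, 1e-12)
  # recovery residual decreases monotonically toward 0 as eta0 grows
  resids <- sapply(c(1e2, 1e3, 1e4, 1e5, Inf), function(e) {
    pe <- burgers_params(0.1, 0.05, 2, e)
    tre <- burgers_displacement_response(pe, geom$C, prot)
    tre$displacement_m[nrow(tre)]
  })
  expect_true(all(diff(resids) < 1e-15))
  expect_equal(resids[5], 0)
})

test_that("zero-force protocol produces zero displacement", {
  prot0 <- force_protocol(F0 = 0)
  tr <- burgers_displacement_response(fix_liquid(), fix_geom()$C, prot0)
  expect_true(all(tr$displacement_m == 0))
})

test_that("default protocol reproduces the experimental waveform", {
  prot <- fix_protocol()
  expect_equal(prot$t_on, 10)
  expect_equal(prot$t_off, 20)
  expect_equal(prot$n_cycles, 2L)
  expect_equal(prot$dt, 0.5)
  wav <- protocol_waveform(prot)
  expect_equal(nrow(wav), 120)
  expect_equal(sum(wav$phase == "on"), 40)   # 20 samples per 10-s on window
  expect_error(force_protocol(F0 = 110e-9, dt = 11), "dt")
  expect_error(force_protocol(F0 = 110e-9, t_on = 0), "t_on")
})
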