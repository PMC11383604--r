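test_that("compliance conversion is linear, homogeneous, and unit-correct", {
  # hand evaluation with unit tracking: J = C x / F0
  expect_equal(compliance_from_displacement(2e-6, F0 = 110e-9, C = 3.007192e-2,
                                            time_s = 0)$J,
               0.5467622, tolerance = 1e-6)
  x <- c(0, 1e-6, 2e-6)
  cc <- compliance_from_displacement(x, F0 = 110e-9, C = 0.03, time_s = 0:2)
  expect_equal(compliance_from_displacement(3 * x, 110e-9, 0.03, time_s = 0:2)$J,
               3 * cc$J)
  expect_equal(compliance_from_displacement(x, 55e-9, 0.03, time_s = 0:2)$J,
               2 * cc$J)
  expect_true(all(compliance_from_displacement(x * 0, 110e-9, 0.03,
                                               time_s = 0:2)$J == 0))
  expect_error(compliance_from_displacement(x, 0, 0.03, time_s = 0:2), "F0")
  expect_error(compliance_from_displacement(x, 110e-9, -1, time_s = 0:2), "C")
})

test_that("conversion inverts the forward model on the on-phase exactly", {
  p <- fix_liquid(); geom <- fix_geom(); prot <- fix_protocol()
  tr <- burgers_displacement_response(p, geom$C, prot)
  cc <- compliance_from_displacement(tr, F0 = prot$F0, C = geom$C)
  on1 <- cc$phase == "on" & cc$time_s < 10
  expect_equal(cc$J[on1], burgers_creep_compliance(p, cc$time_s[on1]),
               tolerance = 1e-12)
})

test_that("protocol segmentation finds the on/off windows with debouncing", {
  wav <- protocol_waveform(fix_protocol())
  seg <- segment_protocol(wav$force_N, wav$time_s)
  expect_equal(seg$phase, c("on", "off", "on", "off"))
  expect_equal(seg$end - seg$start + 1L, c(20L, 40L, 20L, 40L))
  expect_equal(seg$cycle, c(1L, 1L, 2L, 2L))
  # constant nonzero force: one on-window spanning the series
  seg1 <- segment_protocol(rep(1, 50))
  expect_equal(nrow(seg1), 1L)
  expect_equal(seg1$phase, "on")
  expect_equal(c(seg1$start, seg1$end), c(1L, 50L))
  # single-sample glitches are debounced away
  f <- wav$force_N
  f[15] <- 0            # dropout inside an on window
  f[25] <- 110e-9       # spike inside an off window
  seg2 <- segment_protocol(f, wav$time_s, min_duration = 1)
  expect_equal(seg2$phase, seg$phase)
  expect_equal(seg2$start, seg$start)
  expect_error(segment_protocol(rep(0, 50)), "no applied-force")
})

test_that("Burgers fit recovers generating parameters on noiseless data", {
  geom <- fix_geom(); prot <- fix_protocol()
  cases <- list(fix_liquid(),
                burgers_params(0.02, 0.08, 0.5, 1000),
                burgers_params(1.0, 0.2, 5, 50))
  for (p in cases) {
    fit <- fit_burgers(fix_curve(p, prot, geom))
    expect_equal(fit$Je0, steady_state_compliance(p), tolerance = 1e-6)
    expect_equal(fit$eta0, p$eta0, tolerance = 1e-6)
    expect_equal(fit$params$tau, p$tau, tolerance = 1e-4)
  }
})

test_that("per-cycle QC fits agree with the joint fit on clean data", {
  fit <- fit_burgers(fix_curve())
  expect_length(fit$cycles, 2L)
  for (cy in fit$cycles) {
    expect_equal(cy$params$J1 + cy$params$J2, fit$Je0, tolerance = 1e-6)
    expect_equal(cy$params$eta0, fit$eta0, tolerance = 1e-6)
  }
  # per-cycle pooling also recovers the truth on noiseless input
  fit_pc <- fit_burgers(fix_curve(), pooling = "percycle")
  expect_equal(fit_pc$Je0, 0.15, tolerance = 1e-6)
  expect_equal(fit_pc$eta0, 200, tolerance = 1e-6)
})

test_that("pure Newtonian input drives the elastic compliances to zero", {
  t <- seq(0, 9.5, by = 0.5)
  eta <- 150
  cc <- data.frame(time_s = c(t, t + 10), J = c(t / eta, rep(NA, length(t))),
                   phase = rep(c("on", "off"), each = length(t)))
  cc$J[cc$phase == "off"] <- max(t) / eta   # irrelevant to the on-phase fit
  fit <- fit_burgers(cc)
  expect_lt(fit$Je0, 1e-4 * max(t) / eta)
  expect_equal(fit$eta0, eta, tolerance = 1e-4)
})

test_that("a viscoelastic solid input raises the solid-limit flag", {
  solid <- burgers_params(0.1, 0.05, 2, Inf)
  fit <- fit_burgers(fix_curve(solid))
  expect_true(fit$solid_flag)
  expect_equal(fit$Je0, 0.15, tolerance = 1e-6)
  # the retarded element has relaxed to ~exp(-10) by the end of each off
  # phase, so recoil is complete to ~1e-5
  expect_equal(as.numeric(fit$recovery_ratio), 1, tolerance = 1e-4)
  expect_identical(fit$classification, "viscoelastic_solid")
})

test_that("fit is invariant to the absolute time axis", {
  cc <- fix_curve()
  fit0 <- fit_burgers(cc)
  cc2 <- cc
  cc2$time_s <- cc2$time_s + 1234.5   # absolute acquisition time
  fit2 <- fit_burgers(cc2)
  expect_equal(fit2$Je0, fit0$Je0, tolerance = 1e-10)
  expect_equal(fit2$eta0, fit0$eta0, tolerance = 1e-10)
  expect_equal(fit2$params$tau, fit0$params$tau, tolerance = 1e-8)
})

test_that("fit requires enough on-phase samples and phase information", {
  cc <- fix_curve()
  expect_error(fit_burgers(cc[1:5, ]), "8 samples")
  cc$phase <- NA_character_
  expect_error(fit_burgers(cc), "phase labels")
  # supplying the force series recovers the labels by segmentation
  wav <- protocol_waveform(fix_protocol())
  fit <- fit_burgers(cc, force = wav$force_N)
  expect_equal(fit$Je0, 0.15, tolerance = 1e-6)
})

test_that("recovery ratio matches its closed form and flags degenerate input", {
  p <- fix_liquid()
  cc <- fix_curve(p)
  r <- recovery_ratio(cc)
  r_closed <- 1 - (10 / p$eta0) / burgers_creep_compliance(p, 10)
  expect_equal(as.numeric(r), r_closed, tolerance = 0.01)
  expect_length(attr(r, "per_cycle"), 2L)
  # both cycles agree once the pre-cycle baseline is removed
  expect_lt(diff(range(attr(r, "per_cycle"))), 1e-3)
  # Maxwell material (J2 = 0): R = J1 / (J1 + t_on/eta0)
  pm <- burgers_params(0.1, 0, 2, 100)
  ccm <- fix_curve(pm, force_protocol(F0 = 110e-9, t_on = 10, t_off = 60,
                                      n_cycles = 1, dt = 0.1))
  expect_equal(as.numeric(recovery_ratio(ccm)), 0.1 / (0.1 + 10 / 100),
               tolerance = 0.01)
  # nonpositive end-of-on deformation is flagged, not guessed
  bad <- data.frame(time_s = 0:3, J = c(0, 0, 0, 0),
                    phase = c("on", "on", "off", "off"))
  expect_warning(rb <- recovery_ratio(bad), "undefined")
  expect_true(is.na(rb))
})

test_that("gel classification is thresholded recovery with a single switch", {
  expect_identical(classify_gel(1.0), "viscoelastic_solid")
  expect_identical(classify_gel(0.75), "viscoelastic_liquid")
  expect_identical(classify_gel(0.9), "viscoelastic_solid")  # boundary: solid
  # sweeping eta0 upward at fixed elastic parameters switches exactly once
  etas <- c(10, 30, 100, 300, 1e3, 3e3, 1e4, 1e5, Inf)
  cls <- sapply(etas, function(e) {
    cc <- fix_curve(burgers_params(0.1, 0.05, 2, e))
    classify_gel(recovery_ratio(cc))
  })
  expect_equal(sum(diff(cls == "viscoelastic_solid") != 0), 1L)
  expect_identical(cls[1], "viscoelastic_liquid")
  expect_identical(cls[length(cls)], "viscoelastic_solid")
})

test_that("stress sweep declares one material linear and a force-dependent one not", {
  geom <- fix_geom()
  p <- fix_liquid()
  fits <- lapply(c(50e-9, 110e-9, 460e-9), function(F0) {
    prot <- force_protocol(F0 = F0)
    fit_burgers(fix_curve(p, prot, geom), force_applied = F0, qc_cycles = FALSE)
  })
  sw <- stress_sweep_linearity(fits)
  expect_identical(sw$verdict, "linear")
  expect_lt(sw$cv_Je0, 1e-6)
  expect_lt(abs(sw$slope), 1e-6)
  # constructed nonlinear fixture: Je0 doubling with force -> slope ~ 1
  fake <- lapply(1:3, function(i) {
    f <- fits[[1]]
    f$Je0 <- 0.1 * 2^(i - 1)
    f$force_applied <- 100e-9 * 2^(i - 1)
    f
  })
  sw2 <- stress_sweep_linearity(fake)
  expect_identical(sw2$verdict, "nonlinear")
  expect_equal(sw2$slope, 1, tolerance = 0.05)
  expect_error(stress_sweep_linearity(fits[1:2]), "3 distinct")
})
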