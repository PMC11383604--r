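test_that("trace simulation is deterministic given the seed and exact when noiseless", {
  p <- fix_liquid(); geom <- fix_geom(); prot <- fix_protocol()
  clean <- simulate_trace(p, geom, prot, noise_sigma = 0, seed = 1)
  forward <- burgers_displacement_response(p, geom$C, prot)
  expect_identical(clean$displacement_m, forward$displacement_m)
  a <- simulate_trace(p, geom, prot, noise_sigma = 0.02, seed = 7)
  b <- simulate_trace(p, geom, prot, noise_sigma = 0.02, seed = 7)
  d <- simulate_trace(p, geom, prot, noise_sigma = 0.02, seed = 8)
  expect_identical(a$displacement_m, b$displacement_m)
  expect_false(identical(a$displacement_m, d$displacement_m))
})

test_that("simulators leave the caller's RNG stream untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(simulate_trace(fix_liquid(), fix_geom(), fix_protocol(),
                           noise_sigma = 0.02, seed = 3))
  invisible(simulate_cohort(cohort_spec(n_donors = 2, seed = 4)))
  expect_identical(.Random.seed, before)
})

test_that("empirical noise SD matches the requested sigma", {
  p <- fix_liquid(); geom <- fix_geom()
  prot <- force_protocol(F0 = 110e-9, t_on = 10, t_off = 20, n_cycles = 9,
                         dt = 0.25)   # 1080 samples
  clean <- burgers_displacement_response(p, geom$C, prot)
  noisy <- simulate_trace(p, geom, prot, noise_sigma = 0.02, seed = 5)
  resid <- noisy$displacement_m - clean$displacement_m
  target <- 0.02 * (prot$F0 / geom$C) * steady_state_compliance(p)
  expect_equal(sd(resid), target, tolerance = 0.05)
})

test_that("simulated traces pass the pipeline's own protocol segmentation", {
  tr <- simulate_trace(fix_liquid(), fix_geom(), fix_protocol(),
                       noise_sigma = 0.02, seed = 2)
  seg <- segment_protocol(tr$force_N, tr$time_s)
  expect_equal(seg$phase, c("on", "off", "on", "off"))
  expect_equal(max(seg$cycle), 2L)
})

test_that("cohort generation is reproducible and validates its effects", {
  s <- cohort_spec(seed = 3)
  a <- simulate_cohort(s)
  b <- simulate_cohort(s)
  expect_identical(a$table, b$table)
  expect_identical(a$traces[[1]]$displacement_m, b$traces[[1]]$displacement_m)
  expect_equal(nrow(a$table), 5 * 3 * 2)
  # IL-13 must lower compliance and raise viscosity
  expect_error(cohort_spec(il13_effect = c(Je0 = 2, eta0 = 5)), "IL-13")
  expect_error(cohort_spec(il13_effect = c(Je0 = 0.3, eta0 = 0.5)), "IL-13")
  expect_error(cohort_spec(inserts_per_donor = 4), "2 or 3")
})

test_that("ground-truth condition effects are exactly recoverable without noise", {
  s <- cohort_spec(noise_sigma = 0, insert_cv = 0,
                   il13_effect = c(Je0 = 0.3, eta0 = 5), seed = 6)
  coh <- simulate_cohort(s)
  tab <- fit_cohort(coh, qc_cycles = FALSE)
  per_donor <- aggregate_donor(tab)
  ctrl <- per_donor[per_donor$condition == "control", ]
  il13 <- per_donor[per_donor$condition == "il13", ]
  il13 <- il13[match(ctrl$donor, il13$donor), ]
  expect_equal(il13$Je0 / ctrl$Je0, rep(0.3, nrow(ctrl)), tolerance = 1e-4)
  expect_equal(il13$eta0 / ctrl$eta0, rep(5, nrow(ctrl)), tolerance = 1e-4)
  # fits recover each insert's truth
  expect_equal(tab$Je0, tab$true_Je0, tolerance = 1e-6)
  expect_equal(tab$eta0, tab$true_eta0, tolerance = 1e-6)
})

test_that("null cohorts are exchangeable across conditions", {
  s <- cohort_spec(il13_effect = c(Je0 = 1, eta0 = 1),
                   dtt_effect = c(Je0 = 1, eta0 = 1),
                   condition_forces = c(control = 110e-9, il13 = 110e-9,
                                        il13_dtt = 110e-9),
                   seed = 8)
  s0 <- cohort_spec(il13_effect = c(Je0 = 1, eta0 = 1),
                    dtt_effect = c(Je0 = 1, eta0 = 1),
                    insert_cv = 0, noise_sigma = 0,
                    condition_forces = c(control = 110e-9, il13 = 110e-9,
                                         il13_dtt = 110e-9),
                    seed = 8)
  tab <- simulate_cohort(s0)$table
  # with unit effects and no replicate jitter, every condition carries the
  # same latent donor parameters
  for (d in unique(tab$donor)) {
    sub <- tab[tab$donor == d, ]
    expect_equal(diff(range(sub$true_Je0)), 0)
    expect_equal(diff(range(sub$true_eta0)), 0)
  }
})

test_that("z-profile generator validates layer ordering", {
  expect_error(simulate_zprofiles(list(cell_surface = 70, wire_center = 10)),
               "ordered")
  expect_error(simulate_zprofiles(list(wire_center = 10)), "cell_surface")
  prof <- simulate_zprofiles(list(cell_surface = 10, wire_center = 67),
                             noise = 0.05, seed = 2)
  expect_s3_class(prof, "zprofile_set")
  expect_true(all(prof$channels$ch_647 >= 0))
})

test_that("image-stack generator is deterministic and renders a still wire still", {
  st0 <- simulate_image_stack(rep(0, 4), noise_sd = 0)
  for (f in 2:4) expect_identical(st0[, , f], st0[, , 1])
  a <- simulate_image_stack(c(0, 1.2), noise_sd = 0.1, seed = 9)
  b <- simulate_image_stack(c(0, 1.2), noise_sd = 0.1, seed = 9)
  expect_identical(a, b)
})
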