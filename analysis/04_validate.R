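#!/usr/bin/env Rscript

# Step 4 - method validation on ground truth: calibration worked examples,
# drag-coefficient oracle, noiseless forward/inverse identity, noisy
# parameter recovery, recovery-ratio closed form, stress-sweep linearity
# and the render->track round trip.
#
# Writes: results/validation.json

suppressPackageStartupMessages(library(mmwr))
dir.create("results", showWarnings = FALSE)

seed <- 20260924 %% 2147483647
geom <- wire_geometry(h = 57e-6)
prot <- force_protocol(F0 = 110e-9)
liquid <- burgers_params(0.1, 0.05, 2, 200)
v <- list()

cal <- calibration_from_point(0.6, 110e-9)
v$force_at_2p5A_nN <- force_from_current(cal, 2.5) * 1e9
cat(sprintf("Calibration: 2.5 A -> %.1f nN (printed instrument value: 460 nN)\n",
            v$force_at_2p5A_nN))

x <- geom$h / geom$r
v$drag_relerr_vs_logform <-
  abs(geom$C - 4 * pi * geom$L / log(x + sqrt(x^2 - 1))) / geom$C
cat(sprintf("Drag: C = %.4g m, rel. diff vs log-form oracle %.1e\n",
            geom$C, v$drag_relerr_vs_logform))

set.seed(seed)
worst <- 0
for (i in 1:100) {
  p <- burgers_params(10^runif(1, -2, 1), 10^runif(1, -2, 1),
                      10^runif(1, log10(0.25), log10(25)), 10^runif(1, 1, 4))
  f <- fit_burgers(compliance_from_displacement(
    burgers_displacement_response(p, geom$C, prot), prot$F0, geom$C),
    qc_cycles = FALSE)
  worst <- max(worst, abs(f$Je0 - steady_state_compliance(p)) /
                 steady_state_compliance(p), abs(f$eta0 - p$eta0) / p$eta0)
}
v$noiseless_recovery_max_relerr <- worst
cat(sprintf("Noiseless identity over 100 draws: worst rel. error %.1e\n", worst))

errs <- sapply(1:50, function(s) {
  tr <- simulate_trace(liquid, geom, prot, noise_sigma = 0.02, seed = seed + s)
  f <- fit_burgers(compliance_from_displacement(tr, prot$F0, geom$C),
                   qc_cycles = FALSE)
  c(abs(f$Je0 - 0.15) / 0.15, abs(f$eta0 - 200) / 200)
})
v$noisy_median_relerr_Je0 <- median(errs[1, ])
v$noisy_median_relerr_eta0 <- median(errs[2, ])
cat(sprintf("Noisy recovery (2%% noise, 50 seeds): median errors Je0 %.2f%%, eta0 %.2f%%\n",
            100 * v$noisy_median_relerr_Je0, 100 * v$noisy_median_relerr_eta0))

cc <- compliance_from_displacement(
  burgers_displacement_response(liquid, geom$C, prot), prot$F0, geom$C)
v$recovery_ratio <- as.numeric(recovery_ratio(cc))
v$recovery_ratio_closed_form <-
  1 - (10 / liquid$eta0) / burgers_creep_compliance(liquid, 10)
cat(sprintf("Recovery ratio %.4f vs closed form %.4f\n",
            v$recovery_ratio, v$recovery_ratio_closed_form))

fits <- lapply(c(50e-9, 110e-9, 460e-9), function(F0) {
  pr <- force_protocol(F0 = F0)
  fit_burgers(compliance_from_displacement(
    burgers_displacement_response(liquid, geom$C, pr), F0, geom$C),
    force_applied = F0, qc_cycles = FALSE)
})
sw <- stress_sweep_linearity(fits)
v$stress_sweep_verdict_linear <- as.integer(sw$verdict == "linear")
cat(sprintf("Stress sweep 50/110/460 nN: %s (CV Je0 %.1e, log-log slope %.1e)\n",
            sw$verdict, sw$cv_Je0, sw$slope))

tr <- burgers_displacement_response(liquid, geom$C, prot)
px <- tr$displacement_m / max(tr$displacement_m) * 6
rel <- px - px[1]
t_errs <- unlist(lapply(1:20, function(s) {
  st <- simulate_image_stack(px, noise_sd = 0.1, seed = seed + s)
  track_wire_displacement(st)$displacement_px - rel
}))
v$tracking_rms_px <- sqrt(mean(t_errs^2))
v$tracking_bias_px <- mean(t_errs)
cat(sprintf("Tracking round trip at SNR 10 (20 seeds): RMS %.3f px, bias %+.4f px\n",
            v$tracking_rms_px, v$tracking_bias_px))

jsonlite::write_json(v, "results/validation.json", auto_unbox = TRUE, digits = NA)
cat("Validation summary written to results/validation.json\n")
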