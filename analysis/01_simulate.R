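#!/usr/bin/env Rscript

# Step 1 - generate the synthetic study inputs with known ground truth:
# a paired donor cohort (control / IL-13 / IL-13 + DTT, 5 donors, 2 inserts
# per condition, 2% displacement noise) measured under the standard
# step-force protocol (10 s on / 20 s off, twice, sampled every 500 ms),
# plus the z-profile scan used to localize the wire above the cell layer.
#
# Writes: results/cohort_truth.csv, results/wire_geometry.json
# The traces themselves are regenerated deterministically from the seed in
# later steps, so only the ground-truth table is persisted.

suppressPackageStartupMessages(library(mmwr))
dir.create("results", showWarnings = FALSE)

seed <- 20260924 %% 2147483647

# wire height from a (synthetic) multi-channel z-scan, as in a real session
prof <- simulate_zprofiles(list(cell_surface = 10, wire_center = 67,
                                mucus_top = 80), noise = 0.05, seed = seed)
layers <- locate_layers(prof)
cat(sprintf("Localized layers: cell surface %.2f um, wire centre %.2f um -> wire height %.2f um\n",
            layers$cell_surface, layers$wire_center, layers$wire_height_um))

geom <- wire_geometry(h = layers$wire_height_um * 1e-6)
cat(sprintf("Drag coefficient C = %.4g m for r = %.1f um, L = %.1f mm\n",
            geom$C, geom$r * 1e6, geom$L * 1e3))
jsonlite::write_json(list(r_m = geom$r, L_m = geom$L, h_m = geom$h, C_m = geom$C),
                     "results/wire_geometry.json", auto_unbox = TRUE, digits = NA)

spec <- cohort_spec(seed = seed)
cohort <- simulate_cohort(spec, geom = geom)
utils::write.csv(cohort$table, "results/cohort_truth.csv", row.names = FALSE)
cat(sprintf("Simulated %d traces (%d donors x %d conditions x %d inserts), seed %d\n",
            nrow(cohort$table), spec$n_donors, length(spec$effects),
            spec$inserts_per_donor, seed))
cat("Condition effects on (Je0, eta0): IL-13 x(0.3, 20); DTT restores control.\n")
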