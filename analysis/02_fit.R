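#!/usr/bin/env Rscript

# Step 2 - the creep inference chain on every trace: displacement ->
# compliance (J = C x / F0) -> Burgers fit on the force-on windows ->
# recovery ratio and liquid/solid classification.
#
# Reads:  results/cohort_truth.csv (for the seed/geometry consistency check)
# Writes: results/cohort_fits.csv

suppressPackageStartupMessages(library(mmwr))

truth <- utils::read.csv("results/cohort_truth.csv")
seed <- truth$seed[1]  # per-trace seeds derive from the cohort seed
geom_js <- jsonlite::read_json("results/wire_geometry.json", simplifyVector = TRUE)
geom <- wire_geometry(r = geom_js$r_m, L = geom_js$L_m, h = geom_js$h_m)

spec <- cohort_spec(seed = 20260924 %% 2147483647)
cohort <- simulate_cohort(spec, geom = geom)
stopifnot(identical(cohort$table$trace_id, truth$trace_id))

tab <- fit_cohort(cohort)
utils::write.csv(tab, "results/cohort_fits.csv", row.names = FALSE)

rel_err <- abs(tab$Je0 - tab$true_Je0) / tab$true_Je0
cat(sprintf("Fitted %d traces; median |Je0 error| %.2f%%, median |eta0 error| %.2f%%\n",
            nrow(tab), 100 * median(rel_err),
            100 * median(abs(tab$eta0 - tab$true_eta0) / tab$true_eta0)))
for (cond in unique(tab$condition)) {
  sub <- tab[tab$condition == cond, ]
  cat(sprintf("  %-9s mean Je0 %.4g 1/Pa, mean eta0 %.4g Pa s, recovery %.3f, solid %d/%d\n",
              cond, mean(sub$Je0), mean(sub$eta0), mean(sub$recovery_ratio),
              sum(sub$classification == "viscoelastic_solid"), nrow(sub)))
}
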