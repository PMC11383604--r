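#!/usr/bin/env Rscript

# Step 3 - cohort statistics: aggregate insert replicates to per-donor
# means, then ratio paired t tests (paired t on log within-donor ratios)
# for IL-13 vs control, IL-13+DTT vs IL-13, and IL-13+DTT vs control, on
# both steady-state compliance and zero-shear viscosity.
#
# Reads:  results/cohort_fits.csv
# Writes: results/comparisons.json, results/report.md

suppressPackageStartupMessages(library(mmwr))

tab <- utils::read.csv("results/cohort_fits.csv")
cmp <- compare_conditions(tab)

for (nm in names(cmp)) {
  x <- cmp[[nm]]
  cat(sprintf("%-24s Je0 GM ratio %6.3g (p=%.2g)  eta0 GM ratio %6.3g (p=%.2g)  -> %s, %s\n",
              nm, x$Je0$gm_ratio, x$Je0$p_value, x$eta0$gm_ratio,
              x$eta0$p_value, x$compliance_direction, x$viscosity_direction))
}

out <- lapply(cmp, function(x) list(
  pair = x$pair, n_donors = x$n_donors,
  Je0 = x$Je0[c("t", "df", "p_value", "gm_ratio")],
  eta0 = x$eta0[c("t", "df", "p_value", "gm_ratio")],
  reading = paste(x$compliance_direction, x$viscosity_direction, sep = ", ")))
jsonlite::write_json(out, "results/comparisons.json", auto_unbox = TRUE,
                     digits = NA)

mean_rr <- tapply(tab$recovery_ratio, tab$condition, mean)
cls <- vapply(mean_rr, classify_gel, character(1))
lines <- c("# Cohort comparison report", "",
           "Per-donor insert means compared by ratio paired t tests (no multiplicity correction; per-comparison reporting).",
           "",
           sprintf("- %s: Je0 ratio %.3g (p = %.2g), eta0 ratio %.3g (p = %.2g)",
                   names(cmp),
                   vapply(cmp, function(x) x$Je0$gm_ratio, 1),
                   vapply(cmp, function(x) x$Je0$p_value, 1),
                   vapply(cmp, function(x) x$eta0$gm_ratio, 1),
                   vapply(cmp, function(x) x$eta0$p_value, 1)),
           "",
           sprintf("Condition-level classification (mean recovery ratio, threshold 0.9): %s.",
                   paste(sprintf("%s = %s (R = %.2f)", names(cls), cls,
                                 mean_rr), collapse = "; ")))
writeLines(lines, "results/report.md")
cat("Report written to results/report.md\n")
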