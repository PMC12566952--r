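#!/usr/bin/env Rscript
# Local sensitivity analysis: one-at-a-time +10% perturbation of GI
# physiology, release, and elimination parameters for both APIs;
# coefficients per Cmax / AUC0-t / Tmax with the |S| >= 0.05 inclusion
# rule that selects virtual-population variants.
# Writes results/sensitivity.csv.

suppressPackageStartupMessages(library(pbbm))
dir.create("results", showWarnings = FALSE)

gi_params <- c(paste0("phys.segment_ph.", gi_segment_names),
               "phys.get_liquid", "phys.get_solid", "phys.sitt",
               "phys.litt", "test_form.td50", "test_form.shape")
elim <- list(metformin = c("drug.elimination.tsmax_spec",
                           "drug.elimination.km"),
             glyburide = c("disp.cl_hepatic"))

all_tabs <- list()
for (drug in c("metformin", "glyburide")) {
  cfg <- study_preset(drug)
  tab <- run_sensitivity(cfg, c(gi_params, elim[[drug]]),
                         t_grid_h = seq(0, 48, by = 0.1))
  tab$drug <- drug
  all_tabs[[drug]] <- tab

  cat(sprintf("\n== %s: parameters ranked by max |S| ==\n", drug))
  agg <- aggregate(abs(s) ~ parameter, tab, max)
  names(agg)[2] <- "max_abs_s"
  agg <- agg[order(-agg$max_abs_s), ]
  agg$included <- agg$max_abs_s >= 0.05
  print(agg, digits = 3, row.names = FALSE)
}
out <- do.call(rbind, all_tabs)
write.csv(out, "results/sensitivity.csv", row.names = FALSE)

cat("\nReading: transit times dominate for the freely soluble,\n")
cat("permeability-limited API; small-intestinal pH dominates for the\n")
cat("poorly soluble weak acid. Parameters below |S| = 0.05 are excluded\n")
cat("from the virtual-population variant list.\n")
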