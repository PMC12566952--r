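#!/usr/bin/env Rscript
# Virtual bioequivalence: 100-subject virtual population with two GI
# states per subject (within-subject variability), balanced TR/RT 2x2
# crossover, test vs reference formulation for each API, crossover
# ANOVA on log Cmax and log AUC0-t, and the combination-level verdict.
# Writes results/vbe_metrics.csv and results/vbe_summary.csv.

suppressPackageStartupMessages(library(pbbm))
dir.create("results", showWarnings = FALSE)
seed <- 2024L
n <- 100

summaries <- list()
metrics <- list()
vbes <- list()
for (drug in c("metformin", "glyburide")) {
  cfg <- study_preset(drug)
  v <- run_vbe(cfg, n = n, seed = seed)
  vbes[[drug]] <- v
  cat(sprintf("\n== %s ==\n", drug))
  print(v)
  m <- v$metrics
  m$drug <- drug
  metrics[[drug]] <- m
  for (met in names(v$be)) {
    b <- v$be[[met]]
    summaries[[paste(drug, met)]] <- data.frame(
      drug = drug, metric = met, n = v$n,
      gmr_pct = round(b$gmr_pct, 2),
      ci_lo = round(b$ci90[1], 2), ci_hi = round(b$ci90[2], 2),
      pass = b$pass)
  }
}

write.csv(do.call(rbind, metrics), "results/vbe_metrics.csv",
          row.names = FALSE)
summary_tab <- do.call(rbind, summaries)
write.csv(summary_tab, "results/vbe_summary.csv", row.names = FALSE)

cat("\nSummary:\n")
print(summary_tab, row.names = FALSE)
cat(sprintf("\nFDC verdict (all four metric x API tests must pass): %s\n",
            fdc_verdict(vbes$metformin, vbes$glyburide)))
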