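#!/usr/bin/env Rscript
# Step 5: calibration models on the SPA-selected feature wavelengths,
# comparison against the full-spectrum grid, per-indicator best-model
# determination (prediction R2, ties to RPD, then RMSEP, then model
# simplicity), and report rendering (summary CSVs, bar charts, winner
# scatter plots, SPA position plots, CNN loss curves).

suppressPackageStartupMessages(library(vinechem))

ds <- read_dataset("results/data/spectra.csv", "results/data/references.csv")

cfg <- pipeline_config(
  ds,
  indicators = indicator_names(),
  preprocessing = c("DT", "SNV", "MSC"),
  models = c("PLS", "SVR"),
  modes = c("full", "spa"),
  spa = spa_config(max_vars = 50, mc_runs = 20, cv_folds = 10, force_size = TRUE, seed = 1),
  seed = 1L
)
grid <- run_grid(cfg, progress = TRUE)
best <- select_best(grid)
paths <- render_reports(grid, best, dir = "results/reports")

cat("\nBest model per indicator:\n")
print(best$winners)
cat("\nWrote", length(paths), "report files under results/reports/\n")
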