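#!/usr/bin/env Rscript
# Step 3: full-wavelength calibration models under the six preprocessing
# methods. PLS and SVR are swept for all six indicators; the CNN, much
# costlier on 1507-point spectra, is run for one representative indicator
# (TSS) at the desk profile of 100 epochs. Results land in
# results/full_grid/.

suppressPackageStartupMessages(library(vinechem))

ds <- read_dataset("results/data/spectra.csv", "results/data/references.csv")
dir.create("results/full_grid", recursive = TRUE, showWarnings = FALSE)

cfg <- pipeline_config(
  ds,
  indicators = indicator_names(),
  preprocessing = c("DT", "FD", "MSC", "SG", "SNV", "SS"),
  models = c("PLS", "SVR"),
  modes = "full",
  seed = 1L
)
grid <- run_grid(cfg, progress = TRUE)

cnn_cfg <- pipeline_config(
  ds,
  indicators = "TSS", preprocessing = c("SNV", "DT"),
  models = "CNN", modes = "full", cnn_epochs = 100L, seed = 1L
)
cnn_grid <- run_grid(cnn_cfg, progress = TRUE)

records <- rbind(grid$records, cnn_grid$records)
utils::write.csv(records, "results/full_grid/grid_summary.csv", row.names = FALSE)

ok <- records[records$status == "ok", ]
cat("\nBest full-spectrum combination per indicator (by prediction R2):\n")
for (ind in unique(ok$indicator)) {
  sub <- ok[ok$indicator == ind, ]
  b <- sub[which.max(sub$pred_r2), ]
  cat(sprintf(
    "  %-5s %s-%s  Rp2 %.3f  RMSEP %.3g  RPD %.2f\n",
    ind, b$preprocessing, b$model, b$pred_r2, b$pred_rmse, b$pred_rpd
  ))
}
dir.create("scratch", showWarnings = FALSE)
saveRDS(list(grid = grid, cnn = cnn_grid), "scratch/full_grid.rds")
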