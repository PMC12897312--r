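#!/usr/bin/env Rscript
# Step 4: SPA feature-wavelength selection, applied per indicator to its
# best-performing preprocessing from step 3 (selection runs on the
# calibration rows only). 80 Monte-Carlo samplings of 10-fold RMSECV
# score the candidate subset sizes; the subset size is fixed at 50, the
# protocol that reports 50 wavelengths per indicator. Selected positions
# and RMSECV curves go to results/selection/.

suppressPackageStartupMessages(library(vinechem))

ds <- read_dataset("results/data/spectra.csv", "results/data/references.csv")
summary_full <- utils::read.csv("results/full_grid/grid_summary.csv")
dir.create("results/selection", recursive = TRUE, showWarnings = FALSE)

ok <- summary_full[summary_full$status == "ok", ]
for (ind in indicator_names()) {
  sub <- ok[ok$indicator == ind, ]
  best_prep <- sub$preprocessing[which.max(sub$pred_r2)]
  y <- ds$references[[ind]]
  split <- spxy_split(ds$spectra, y, 0.7, ind)
  tr <- split$train_indices
  x <- ds$spectra$reflectance
  fp <- fit_preprocessor(best_prep, x[tr, , drop = FALSE],
    wavelengths = as.numeric(ds$spectra$grid)
  )
  xtr <- transform_spectra(fp, x[tr, , drop = FALSE])
  sel <- select_wavelengths(
    xtr, y[tr],
    spa_config(max_vars = 50, mc_runs = 80, cv_folds = 10, force_size = TRUE, seed = 1)
  )
  wl <- as.numeric(ds$spectra$grid)
  jsonlite::write_json(
    list(
      indicator = ind, preprocessing = best_prep,
      selected_indices = sel$selected_indices,
      selected_wavelengths_nm = wl[sel$selected_indices],
      rmsecv_curve = sel$rmsecv_curve
    ),
    file.path("results/selection", paste0("spa_", ind, ".json")),
    auto_unbox = TRUE, digits = NA
  )
  cat(sprintf(
    "%-5s (%s): %d wavelengths, RMSECV min %.4g at size %d\n",
    ind, best_prep, sel$chosen_size, min(sel$rmsecv_curve),
    which.min(sel$rmsecv_curve)
  ))
}
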