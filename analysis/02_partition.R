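#!/usr/bin/env Rscript
# Step 2: SPXY 7:3 partitioning, run once per indicator since the
# response enters the joint X-Y distance. Writes one split CSV per
# indicator under results/splits/ and prints the set sizes
# (134 calibration / 58 prediction for 192 samples).

suppressPackageStartupMessages(library(vinechem))

ds <- read_dataset("results/data/spectra.csv", "results/data/references.csv")
dir.create("results/splits", recursive = TRUE, showWarnings = FALSE)

for (ind in indicator_names()) {
  split <- spxy_split(ds$spectra, ds$references[[ind]], 0.7, ind)
  path <- file.path("results/splits", paste0("split_", ind, ".csv"))
  write_split(split, ds$spectra$sample_ids, path)
  cat(sprintf(
    "%-5s %d calibration / %d prediction -> %s\n",
    ind, length(split$train_indices), length(split$test_indices), path
  ))
}
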