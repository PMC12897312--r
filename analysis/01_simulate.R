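#!/usr/bin/env Rscript
# Step 1: generate the synthetic grape dataset that stands in for the
# study's measurements: 192 samples x 1507 wavelengths (400-1100 nm),
# six indicators (pH, TSS, TA, RS, TPCN, TPCD) expressed through Gaussian
# absorption bands with ripening-driven covariation, plus multiplicative
# scatter, baseline drift, and channel noise. Writes the paired CSVs and
# the generating truth under results/data/.

suppressPackageStartupMessages(library(vinechem))

seed <- 1L
out_dir <- "results/data"

cfg <- default_grape_config(seed = seed)
dataset <- generate_dataset(cfg)
paths <- write_synthetic_dataset(dataset, out_dir)

cat(sprintf(
  "Simulated %d samples x %d wavelengths (seed %d)\n",
  nrow(dataset$spectra$reflectance), length(dataset$spectra$grid), seed
))
cat("Reference value ranges:\n")
for (ind in indicator_names()) {
  v <- dataset$references[[ind]]
  cat(sprintf("  %-5s %8.2f - %8.2f\n", ind, min(v), max(v)))
}
cat("Wrote:", paste(paths, collapse = ", "), "\n")
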