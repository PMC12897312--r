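Package: vinechem
Title: Vis-NIR Chemometrics Pipeline for Grape Quality Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A chemometrics workflow for non-destructive prediction of grape
    quality indicators (pH, total soluble solids, titratable acidity, reducing
    sugars, skin and seed total phenolics) from visible/near-infrared diffuse
    reflectance spectra. Provides a seeded synthetic spectra generator with
    known band-concentration structure, six spectral preprocessing operators
    (SNV, MSC, Savitzky-Golay smoothing and first derivative, detrending,
    standard scaling), SPXY joint X-Y sample partitioning, successive
    projections algorithm (SPA) wavelength selection scored by Monte-Carlo
    cross-validated RMSECV, three regression engines (NIPALS PLS1 with
    cross-validated latent dimension, randomized-search SVR, and a
    one-dimensional convolutional neural network trained by Adam), R2/RMSE/RPD
    evaluation, and a config-driven experiment grid with best-model selection
    and reporting.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    signal
Config/testthat/edition: 3
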