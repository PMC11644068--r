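Package: agbfusion
Title: Multi-Feature Fusion for UAV-Based Potato Above-Ground Biomass Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for estimating potato above-ground
    biomass (AGB) from plot-scale UAV imagery by fusing spectral vegetation
    indices, gray-level co-occurrence matrix texture, canopy cover, growing
    degree days, and a cultivar-dependent growth process ratio (GPR).
    Includes a synthetic UAV scene generator emulating three factorial field
    experiments (cultivar x density, cultivar x nitrogen, nitrogen x
    potassium), two feature-selection routes (Boruta shadow features with
    variance-inflation screening, and Pearson top-k ranking), and a
    six-algorithm regression comparison (random forest, partial least
    squares, multiple/simple linear, ridge, lasso) evaluated with R2, RMSE,
    rRMSE and MAE on a stratified train/test split.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    tiff,
    EBImage,
    ranger,
    glmnet,
    mixOmics,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
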