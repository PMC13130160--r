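Package: twpscan
Title: Detection of Tire-Wear Particles in Tissue by Simulated LA-ICP-MS
    Elemental Imaging and Random-Forest Pixel Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates laterally resolved laser-ablation ICP-MS (LA-ICP-MS)
    elemental imaging of zebrafish gut sections containing tire-wear particles
    (TWPs), and implements the full detection workflow on those data: phantom
    scenes with ground truth, transient multielement signal synthesis with
    laser-log bookkeeping, background correction and NIST612 bracketing-standard
    normalization, laser-log-aligned image reconstruction, bulk elemental
    fingerprint chemometrics (PCA biplots, Ward hierarchical clustering,
    standardized heatmaps), percentile-threshold training-label extraction, a
    pixelwise binary random-forest classifier tuned by out-of-bag error, and
    particle detection and sizing including the geometric minimum detectable
    particle diameter.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    ape,
    optparse,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
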