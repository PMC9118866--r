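Package: uavlai
Title: Wheat Leaf Area Index Estimation from Multi-Sensor UAV Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis pipeline for estimating wheat leaf
    area index (LAI) from co-registered multi-sensor unmanned aerial
    vehicle (UAV) rasters: five-band multispectral reflectance, thermal
    infrared, and photogrammetric surface/terrain models. Provides a
    synthetic scene generator with known ground truth, support-vector
    soil-background masking with confusion-matrix accuracy assessment,
    a registry of fifteen vegetation indices plus canopy height model
    (CHM) and normalized relative canopy temperature (NRCT) feature
    rasters with explicit undefined-value semantics, plot-level zonal
    statistics, and a model-comparison harness (random forest,
    support-vector, and multiple linear regression) with
    importance-based feature selection and per-pixel LAI prediction
    maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    randomForest,
    jsonlite,
    tiff,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
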