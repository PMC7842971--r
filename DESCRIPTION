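Package: forstruct
Title: Forest Structure Extrapolation by Random-Forest Proximity k-NN
    Imputation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Wall-to-wall extrapolation of gridded forest structural
    attributes (e.g. lidar-derived canopy height percentiles and canopy
    cover) from multispectral satellite image time series and terrain
    predictors. Provides a raster-native toolchain: grid harmonization
    (resampling, extent matching, focal smoothing, edge buffering,
    tiling), spectral indices (NDVI, NBR, Tasseled Cap), temporal summary
    metrics of annual index series (median, interquartile range,
    Theil-Sen slope), structure-guided stratified sampling with a
    minimum-distance constraint, k-nearest-neighbour imputation driven by
    a random-forest proximity measure with chunked wall-to-wall
    prediction, cross-validated accuracy reporting and permutation-based
    predictor importance, plus a fully synthetic seeded scene generator
    so the entire pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ggplot2,
    jsonlite,
    ranger,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
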