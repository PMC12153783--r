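Package: bioclimzone
Title: Bioclimatic Zoning for Dairy Cattle from Gridded Climate Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for delineating livestock heat-stress zones from
    georeferenced climate data. Computes the Temperature-Humidity Index
    (THI) and regression-based estimates of the decrease in milk
    production, classifies heat-stress and climate-variability levels,
    derives the Standardized Precipitation Index (SPI) from gamma fits to
    annual precipitation, and interpolates index surfaces by ordinary
    kriging with semivariogram model fitting, leave-one-out
    cross-validation and spatial-dependence diagnostics. A synthetic
    climate-field generator produces spatially autocorrelated test data
    so the whole pipeline is reproducible without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    geosphere,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
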