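Package: isleva
Title: Island Ecological Vulnerability Assessment and Impact-Mechanism
    Diagnostics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Raster-based ecological vulnerability assessment of islands
    under the exposure-sensitivity-adaptability (E-S-A) framework:
    indicator standardization against reference values, weighted element
    aggregation, equal-weight objective aggregation, a geometric-mean
    vulnerability index with five-level classification, discretization of
    assessment layers into ordinal states, pairwise conditional-probability
    analysis of indicator states (conditional and optimal state subsets),
    entropy-difference ranking of key indicators, and identification of
    spatial-pattern promotion regions with exact hectare accounting.
    Includes a deterministic synthetic island generator for end-to-end
    validation and a file-based pipeline for running the stages from
    plain-text (ESRI ASCII grid) rasters.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
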