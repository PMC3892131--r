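Package: stalkscreen
Title: High-Throughput Biofuel Feedstock Screening from FTIR Spectra and
    Stalk Geometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A holistic screening toolkit for sweet sorghum and similar
    grass biofuel feedstocks. Predicts juice sucrose, glucose and fructose
    concentrations and cell-wall enzymatic digestibility from mid-infrared
    (FTIR-ATR) spectra using NIPALS partial least squares regression with
    Savitzky-Golay derivatives, extended multiplicative scatter correction
    (EMSC), leave-one-out cross-validation, jackknife confidence-interval
    variable selection and offset/slope bias correction. Extrapolates
    measurements on a single sampled internode to whole stalks through a
    conical-frustum taper model and combines juice volume, sugar
    concentration, biomass and digestibility into a total fermentable
    sugar yield per stalk. Includes synthetic-data generators (Gaussian
    band mixtures on a water background, scatter-corrupted bagasse
    spectra, frustum-taper stalk populations) so the full pipeline can be
    exercised and validated without instrument or field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    signal,
    withr,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    optparse
Config/testthat/edition: 3
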