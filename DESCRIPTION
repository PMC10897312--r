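Package: mangroveflux
Title: Mapping Mangrove Carbon Assimilation from UAV Multispectral Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify carbon assimilation in mangrove stands from
    UAV multispectral surveys. Covers vicarious radiometric correction of raw
    frames to surface reflectance, vegetation-index and canopy-height-model
    feature layers, multiple linear regression of ground-measured leaf area
    index (LAI) on the image predictors with leave-one-out cross-validation
    and LMG relative-importance decomposition, and per-pixel upscaling of
    leaf-level net photosynthesis to annual carbon-assimilation maps, area
    totals and rates. Includes a seeded synthetic-scene generator so the
    whole pipeline is testable without field data, and a staged pipeline
    runner with provenance manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
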