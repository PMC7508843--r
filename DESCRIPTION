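Package: drusenseq
Title: Longitudinal Drusen Biomarkers and Stacked-LSTM Risk Models for
    Exudative Conversion in AMD
Version: 0.1.0
Authors@R:
    person("drusenseq", "developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for predicting a first exudation event in non-exudative
    age-related macular degeneration (AMD) eyes from longitudinal SD-OCT
    drusen quantification. Provides extraction of 21 drusen imaging
    biomarkers (counts, areas, volumes, extent, density, height, slope and
    normalized reflectivity) from segmented OCT volumes; outcome labeling
    with horizon-specific censoring over 3- to 21-month prediction windows;
    padding-based sequence augmentation; a two-layer stacked LSTM trained
    with a time-distributed weighted cross-entropy loss (one model per
    horizon); patient-level stratified cross-validation with ROC/PR
    evaluation in four settings (overall, visit-variant, external cohort,
    patient-level fixed-visit); and a synthetic-data module generating
    spherical-cap drusen phantoms with closed-form geometry and longitudinal
    cohorts with a planted feature-dependent discrete-time hazard.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
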