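Package: deltagbc
Title: Pharmacological fMRI Analysis of Global Brain Connectivity and
    Multi-Dimensional Drug Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for analysing pharmacological resting-state
    fMRI at the parcel level. Computes denoised functional connectivity and
    global brain connectivity (GBC) maps from parcellated BOLD time series
    with motion scrubbing, high-pass filtering and nuisance regression;
    performs principal component analysis of drug-minus-placebo GBC maps
    with parcel-shuffle permutation significance; quantifies effective
    dimensionality via the participation ratio with equal-n subsampling;
    tests map-to-map correlations against spatial-autocorrelation-matched
    surrogate maps (variogram matching); runs behavioral PCA with
    column-wise permutation nulls and PANSS subscale scoring; and maps
    behavior onto GBC via mass-univariate regression with max-statistic or
    TFCE permutation correction. A synthetic-data generator with planted
    ground truth drives recovery tests for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
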