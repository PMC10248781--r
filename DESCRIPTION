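Package: phenofuzz
Title: Digital Phenotyping of Depression from Passive Smartphone Sensing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for smartphone digital phenotyping of
    adolescent depression: generation of synthetic cohorts of raw sensor
    event streams (GPS fixes, gyroscope bursts, call and text-message logs,
    screen sessions, image counts, medication doses) with planted group
    effects and clinical score trajectories; extraction of daily behavioural
    features (movement distance, rotational momentum, communication and
    screen-use summaries) into a SummarizedExperiment-derived container with
    three per-feature representations (raw, absolute deviation from the
    subject-week mean, weekly standard deviation); feature ranking and
    backward elimination with a neural network with weighted fuzzy
    membership functions (NEWFM); deep neural network and radial-basis
    support vector machine classification under subject-level repeated
    3-fold cross-validation; averaged-rank feature importance; and clinical
    group statistics (responder labelling, t tests, Fisher exact test,
    baseline characteristic tables).
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    geosphere,
    e1071,
    S4Vectors,
    SummarizedExperiment,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'constants.R'
    'AllGenerics.R'
    'AllClasses.R'
    'RcppExports.R'
    'phenofuzz-package.R'
    'synthgen.R'
    'features.R'
    'newfm.R'
    'classifiers.R'
    'evaluation.R'
    'clinstats.R'
    'io.R'
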