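Package: scrawl
Title: Online Handwriting Kinematics and Dysgraphia Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing online handwriting recorded by digitizer
    tablets. Reads and validates SVC-style pen trajectories (position, time,
    surface-contact flag, azimuth, altitude, pressure), segments recordings
    into on-surface and in-air movement, derives kinematic signals (velocity,
    acceleration, jerk and their components), assembles canonical per-task
    feature vectors (133 on-surface, 112 in-air) and merged per-subject
    vectors (1176 features), and benchmarks dysgraphia classifiers
    (AdaBoost, random forest, SVM) under repeated stratified k-fold
    cross-validation with accuracy, specificity and sensitivity reporting.
    Includes a seed-deterministic synthetic handwriting-cohort generator with
    tunable group effects so the full pipeline can be exercised without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    randomForest,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
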