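Package: glandrisk
Title: Gland Histomorphometry and Recurrence Risk Classification for
    Early-Stage Colon Adenocarcinoma Histology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative gland histomorphometry for early-stage colon
    adenocarcinoma (ECA) tissue-microarray images. Segments glands with a
    lumen-seeded classical pipeline (or imports external contours), extracts
    orientation co-occurrence ("tensor") disorder features, shape and size
    descriptors including box-counting fractal dimension, selects prognostic
    features by minimum-redundancy-maximum-relevance, trains and locks a
    recurrence classifier (SVM, random forest, or linear discriminant) under
    stratified five-fold cross-validation, and evaluates predictions with
    confusion metrics, Kaplan-Meier/log-rank and Cox proportional-hazards
    survival statistics. A synthetic glandular-tissue cohort generator with
    controllable orientation disorder and outcome linkage makes every stage
    testable end to end without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    MASS,
    e1071,
    jsonlite,
    randomForest,
    stats,
    survival,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
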