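Package: lodgescore
Title: Wheat Lodging Assessment, Image-Based Lodged-Area Estimation, and
    Predictive Model Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for field assessment of lodging in wheat: crop angle of
    inclination from plumb-bob height pairs, quadrant-protocol lodged-area
    aggregation, the normalized lodging score index and its severity
    classes, lodged-area estimation from canopy RGB photographs by CIELAB
    channel clipping, and a harness comparing stepwise multiple linear
    regression, a feed-forward neural network, support vector regression,
    and random forest as predictors of the lodging score. A synthetic-data
    module generates trait tables with planted moments and correlation
    structure, plumb-bob measurements, and canopy images with known lodged
    fraction so every stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils,
    e1071,
    randomForest,
    png,
    jsonlite,
    yaml,
    Matrix,
    MASS,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    withr
Config/testthat/edition: 3
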