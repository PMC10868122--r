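Package: m1apred
Title: Prediction of 1-Methyladenosine Sites in RNA with Moment-Based
    Features and Ensemble Classifiers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Encodes fixed-length RNA windows centred on a candidate
    adenosine into a 522-dimensional feature vector built from raw,
    central and Hahn statistical moments of position-relative incidence
    matrices, k-mer frequency vectors and accumulative position
    incidence vectors, and trains blending, bagging and boosting
    ensemble classifiers to call 1-methyladenosine (m1A) modification
    sites. Includes stratified independent-split and k-fold evaluation,
    confusion-matrix metrics, AUROC, two-proportion z, McNemar and
    resampled paired t significance tests, and a synthetic window
    generator for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    class,
    e1071,
    nnet,
    ranger,
    rpart,
    stats,
    utils,
    xgboost
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
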