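Package: rppgconf
Title: Motion-Based Confidence Scores for Remote Photoplethysmography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assess the reliability of camera-based heart-rate
    measurements. Extracts blood volume pulse signals from face video via the
    GREEN, CHROM and POS methods, estimates heart rate on 12-second sliding
    windows, computes four per-window motion features (temporal perceptual
    information, face motion along x and y, and face size motion), and trains
    classifiers that turn those features into a continuous confidence score
    for each heart-rate estimate, evaluated threshold-free with ROC/AUC under
    subject-stratified cross-validation. Includes a deterministic synthetic
    face-video generator with known embedded pulse and controlled motion so
    the full pipeline can be exercised without access to rPPG video datasets.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    rpart,
    MASS,
    e1071,
    class,
    nnet,
    grDevices,
    stats,
    utils,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
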