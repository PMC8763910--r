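Package: pdsense
Title: Multi-Modality Digital Biomarkers for Parkinson's Disease Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating smartphone-sensor digital
    biomarkers of Parkinson's disease. Generates realistic synthetic cohorts
    of finger-tapping (accelerometer and screen-coordinate), gait and
    sustained-phonation records with severity-coupled disease effects;
    applies batch-wise normalization and data augmentation (time scaling,
    magnitude scaling, quaternion 3D rotation, 2D rotation); trains compact
    one-dimensional convolutional classifiers with a bounded adaptive
    optimizer; performs individual-level repeated cross-validation with
    record pulling (max or mean) to guard against record-level leakage;
    fuses per-modality scores by late averaging; and compares model scores
    against self-reported symptom ratings with rank-based metrics (ROC AUC,
    precision-recall AUC) and Pearson correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
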