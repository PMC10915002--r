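Package: painstate
Title: Spontaneous Pain State Classification from Cortical Calcium Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies spontaneous pain, non-pain, and drug-induced
    analgesic states from region-of-interest (ROI) calcium traces recorded
    in primary somatosensory cortex. Implements Gaussian denoising,
    baseline-percentile delta-F/F and Z-score normalization, movement
    partitioning from a motion-energy trace, handcrafted activity-share
    difference (D) features with ROC-AUC screening, PCA reduction to six
    components, a dense-layer three-class classifier with false-label
    management, and leave-one-subject-out cross-validation. A synthetic
    cohort generator with ground-truth sidecars makes the whole pipeline
    testable without animal recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nnet,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
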