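Package: dmnfuse
Title: Multimodal 3D Convolutional Classification of Alzheimer's Disease
    from Default-Mode-Network Connectivity and Clinical Scores
Version: 0.1.0
Authors@R:
    person("dmnfuse", "maintainers", email = "maintainers@dmnfuse.dev",
           role = c("aut", "cre"))
Description: Trains and explains a multimodal 3D convolutional network that
    fuses four default-mode-network (DMN) seed-correlation volumes with six
    normalized neuropsychological scores to discriminate Alzheimer's disease
    (AD) from cognitively normal (CN) participants. Provides a synthetic
    cohort generator with a BIDS-like NIfTI/TSV on-disk layout, min-max
    clinical normalization, flip/rotate augmentation, trilinear resizing,
    leakage-safe leave-one-out cross-validation with a full classification
    metric suite (accuracy, sensitivity, specificity, precision, F1, MCC),
    and perturbation-based per-diagnosis-group feature importance ranking
    with rank-change summaries. The convolutional network, batch
    normalization, dropout and Adam optimizer are implemented natively on
    BLAS matrix operations, so no deep-learning framework is required.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
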