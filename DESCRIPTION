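Package: mkmtl
Title: Sparse Linear and Multikernel Multitask Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Joint regression of several related continuous outcomes (tasks)
    from a shared feature matrix, with row-sparse mixed-norm regularization.
    Implements the linear lq,l1-regularized multitask learner solved by
    accelerated proximal gradient with closed-form lq row projections, and two
    multikernel multitask learners: the lq,l1 variant with simplex kernel
    weights and dual-norm task weights updated in closed form, and the l2,1-lq
    variant over positive semidefinite kernel-space matrices solved by
    projected (mirror) descent. Includes Gram-matrix pool construction with
    unit-trace normalization, per-modality kernel pooling for multimodal
    fusion, evaluation metrics (per-task rMSE and correlation, pooled nMSE and
    weighted R), nested cross-validation for hyperparameter tuning, and a
    synthetic multitask data generator emulating row-sparse linear,
    kernel-nonlinear, and multimodal regimes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
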