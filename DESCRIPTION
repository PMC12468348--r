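Package: retinasr
Title: Hybrid Local-Global Super-Resolution and U-Net Grading of Retinal Fundus Images
Version: 0.1.0
Authors@R: person("RetinaSR", "Maintainers", email = "maintainers@retinasr.dev", role = c("aut", "cre"))
Description: A two-stage pipeline for diabetic-retinopathy screening on grayscale
    fundus images. Stage one enhances low-resolution images with a hybrid
    local-global super-resolution network built from deformable convolutions,
    non-local (inter-pixel) attention, and a 2x2-patch transformer, trained with
    an MSE objective against high-resolution targets. Stage two grades the
    enhanced images into the five ICDR severity classes with a U-Net style
    classifier (RefineNet-U) whose decoder output feeds a dropout/dense/softmax
    head. All network numerics (forward and backward passes, Adam optimisation)
    are implemented in R and C++ with no external deep-learning runtime, and a
    seeded synthetic-fundus generator provides graded phantoms and LR/HR training
    pairs so the whole pipeline runs end to end without any data download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: zlib
Config/testthat/edition: 3
RoxygenNote: 7.3.3
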