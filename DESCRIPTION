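Package: gastroq
Title: Q-Learning Classification and Attention U-Net Segmentation for
    Gastrointestinal Endoscopy Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-phase analysis framework for gastrointestinal endoscopy
    imagery. Phase one classifies images with a compact convolutional network
    whose frozen 64-dimensional embedding is discretized into states for a
    tabular Q-learning agent trained with an epsilon-greedy policy and
    plus/minus-one rewards. Phase two segments lesions with an attention-gated
    U-Net trained under pixel-wise binary cross-entropy. Includes dataset
    loading in per-class-folder and image/mask layouts, flip augmentation,
    stratified hold-out splitting, Dice/IoU/pixel-accuracy and confusion-matrix
    metrics, deterministic synthetic fixture generators, and command-line entry
    points. All neural components are trained from scratch with compiled
    convolution primitives.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    Rcpp,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
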