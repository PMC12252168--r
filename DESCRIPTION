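Package: udet
Title: Lightweight Attention-Augmented Detection Networks for Underwater Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and audits lightweight one-stage convolutional detectors for
    underwater organisms (holothurian, echinus, scallop, starfish). Implements a
    YOLOv10n-style backbone and dual detection head together with three
    architectural refinements: a weighted bidirectional feature-pyramid neck with
    P2 integration, a multi-scale attention synergy module (channel, pixel and
    strip-kernel spatial attention) embedded in the neck's C2f bottlenecks, and
    grouped efficient multi-scale attention in backbone and neck. Ships its own
    array-based compute engine with reverse-mode differentiation (Rcpp kernels),
    deterministic structural accounting of learnable parameters and FLOPs, a
    synthetic underwater scene generator with YOLO-format ground truth, and
    COCO-style precision/recall/mAP evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    png
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
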