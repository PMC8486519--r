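Package: leafnet
Title: Leaf Image Recognition with U-Net Segmentation and a Multiloss
    Two-Branch CNN Ensemble
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for plant-leaf species recognition from photographs. A
    U-Net encoder-decoder segments the leaf from its background and the
    enclosing rectangle is cropped; a family of convolutional backbones
    (simple CNN, MobileNet V1, MobileNet V2, EfficientNet B0 with compound
    scaling) classifies the crop; and a two-branch ensemble is trained
    jointly under a multiloss objective that combines the cross-entropy of
    the fused prediction, the per-head cross-entropies, and a weighted
    cosine-similarity coupling between the two heads, with early-fusion
    probability averaging at prediction time. Includes a synthetic leaf
    generator with exact ground-truth masks so the full pipeline is
    trainable and testable without external image collections, and a
    compact reverse-mode neural-network engine with Rcpp kernels that all
    models run on.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    ggplot2,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
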