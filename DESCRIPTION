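Package: axialseg
Title: Parallel CNN-Transformer Segmentation with Masked Axial Attention
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A U-shaped binary segmentation network for lesion images whose
    encoder runs a distance-masked axial-attention transformer branch in
    parallel with residual convolution stages, fuses the two streams with an
    attention-gated global-local fusing module, and trains under a composite
    objective of binary cross-entropy, Dice loss and Canny-edge supervision
    with online hard-example mining. Includes a compact reverse-mode
    automatic-differentiation core, a deterministic synthetic lesion-image
    generator with the standard augmentation suite, confusion-matrix
    evaluation metrics, and training/evaluation/prediction entry points with
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    png,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    optparse,
    jsonlite
Config/testthat/edition: 3
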