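Package: tctnet
Title: Hybrid Transformer-CNN Network for 3D Tumour Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements a hybrid Transformer-CNN encoder-decoder network for
    volumetric tumour segmentation: a four-stage encoder whose attention keys
    and values are produced by strided depth-wise convolutional projection, a
    decoder built from 3D direction-wise convolution blocks, a combined soft
    dice and cross-entropy loss, patch-based training with label-guided
    cropping against class imbalance, and sliding-window inference with
    Gaussian importance weighting. Includes an analytic floating-point
    operation counter, a BraTS-style synthetic phantom generator, NIfTI I/O,
    and a CPU training loop (AdamW with cosine annealing) with hand-derived
    gradients.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
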