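Package: msunet
Title: Multiscale Dilated-Convolution U-Net for Low-Contrast Biomedical
    Image Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An encoder-decoder semantic segmentation toolkit for
    low-contrast grayscale biomedical images such as hippocampus MRI
    slices. Implements a multiscale encoder stem with parallel 1x1,
    asymmetric 3x3/5x5 and dilated (rates 2 and 4) convolution branches, a
    channel-doubling U-net with skip cascades contracting 128x128 to 8x8,
    a deconvolution decoder head restoring input resolution, and a
    region-based soft Dice loss. Includes a seeded synthetic phantom
    generator for low-contrast blob images with paired masks, ROI
    extraction and gray-level standardization, paired image/mask
    augmentation (flips, rotations, translation, elastic deformation),
    overlap metrics (DSC, sensitivity, PPV, IoU), architecture auditing
    utilities (output-size formula, stacked receptive fields, parameter
    counts), and CPU training with Adam and decoupled L2 regularization.
    The convolution, transposed-convolution and batch-normalization
    forward/backward kernels are implemented in C++ via im2col and GEMM.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    RNifti,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
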