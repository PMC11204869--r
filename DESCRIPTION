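Package: plantsr
Title: Super-Resolution of Plant Images with Squeeze-and-Excitation
    Residual Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Single-image super-resolution for plant imagery. Implements the
    PlantSR architecture (residual groups of squeeze-and-excitation attention
    blocks with global feature fusion and pixel-shuffle reconstruction), the
    lightweight SRCNN, VDSR and EDSR reference networks, an
    imresize-compatible bicubic degradation operator for synthesizing
    low-resolution inputs, PSNR/SSIM image-quality metrics and MAE/RMSE
    counting metrics, a patch-based L1/Adam training loop with best-epoch
    checkpointing and transfer-learning fine-tuning, tiled full-image
    inference, and a deterministic generator of plant-like synthetic images
    and counting scenes for end-to-end testing. Networks are trained with
    hand-authored forward/backward passes on BLAS matrix kernels; no external
    deep-learning framework is required.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    png,
    jpeg,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
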