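Package: grrdb
Title: Dense Residual Attention Network for Terahertz Image Denoising
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Implements G-RRDB, a dense-residual convolutional denoiser for
    single-channel terahertz reflectance images of grain. The network combines
    ghost-convolution large-kernel-attention (Ghost-LKA) blocks, residual-in-
    residual dense blocks (RRDB) and dual channel/spatial attention blocks
    (DAB). The package ships a synthetic wheat-kernel phantom generator with
    calibrated Gaussian and source-drift noise models, a CPU training and
    evaluation harness built on a compact reverse-mode automatic
    differentiation engine with 'RcppArmadillo' convolution kernels, PSNR and
    SSIM image-quality metrics, an ablation and graded-noise robustness
    harness, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
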