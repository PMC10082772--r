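Package: blindspot
Title: Self-Supervised Blind-Spot Denoising of OCT B-Scans
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Structured blind-spot (Noise2Void-style) self-supervised denoising
    for optical coherence tomography B-scans in the log-intensity domain.
    Provides a synthetic layered-phantom generator with axially correlated
    speckle-like noise, structured masking with continuous-strip replacement,
    a light-weight depth-2 U-Net family with switchable residual and top-level
    skip connections trained with a masked mean-squared-error objective, a
    streaming buffer pipeline with pseudo-batched inference and seamless
    padding, and an evaluation protocol based on PSNR, SSIM and ROI
    contrast-to-noise ratio.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    png,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    tiff,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
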