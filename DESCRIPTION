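Package: mstar
Title: Multi-Stage Artifact Reduction for Parallel-Beam Tomography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and correction of acquisition artifacts in
    parallel-beam computed tomography. Provides a seedable foam-phantom
    generator, a slice-wise parallel-beam projector and filtered back
    projection, artifact simulation with exactly countable corruption
    (Poisson photon noise, per-detector-pixel ring offsets, zinger
    outliers), mixed-scale dense convolutional networks trained
    sequentially in the projection, sinogram and reconstruction domains
    with bypass connections between stages, classical median-filter and
    wavelet-Fourier baselines with SSIM-maximizing grid search, and
    PSNR/SSIM evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
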