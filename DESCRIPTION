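Package: beamsr
Title: Beamline Super-Resolution of Ultrasound Images and Videos
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Two-stage super-resolution of B-mode ultrasound images acquired
    with a reduced number of scan lines. Lateral beamline decimation emulates
    fast low-resolution acquisition; Keys cubic-convolution interpolation
    restores the full line grid; and a wide-activation residual network
    (WDSR-A style, weight-normalised convolutions) trained with a masked
    logarithmic loss refines the interpolated lines towards the
    high-resolution target. Includes PSNR/SSIM/MAE evaluation with error
    images and histograms, a synthetic speckle-phantom generator for images
    and videos, frame-wise video super-resolution, and the acquisition
    frequency calculator for line-count/frame-rate trade-offs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    yaml,
    stats,
    tools,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
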