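Package: paedenoise
Title: EMI Streak-Noise Removal for Optical-Resolution Photoacoustic Endoscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, removal and evaluation of electromagnetic-interference
    (EMI) streak noise in optical-resolution photoacoustic endoscopy (OR-PAE)
    B-scans. Provides a phantom generator for paired clean/streaked envelope
    images and C-scan volumes, a parametric rain-like streak injector, Hilbert
    envelope detection and ground-truth cleaning, four fully convolutional
    encoder-decoder regressors (U-Net, SegNet, FCN-16s, FCN-8s) trained with
    Adam against a half mean-squared-error loss, restoration metrics (RMSE,
    SSIM, MAE) with per-noise-level sweeps, classical transverse-gradient and
    filtering baselines, and radial maximum amplitude projection (RMAP) of
    denoised volumes into en-face vasculature maps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tiff,
    yaml,
    EBImage,
    Rcpp,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
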