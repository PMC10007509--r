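Package: aedetect
Title: Reconstruction-Based Anomalous Region Detection for Breast
    Ultrasound Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Unsupervised, pixel-level detection of anomalous regions
    (masses, tumors) in breast ultrasonography by reconstruction error.
    Implements three convolutional autoencoder variants trained on
    normal-only images - a plain autoencoder (L1 loss), a variational
    autoencoder (L1 + Gaussian Kullback-Leibler divergence) and a
    sliced-Wasserstein autoencoder (MSE + sliced-Wasserstein distance
    between the latent batch and a standard-normal prior) - together
    with anomaly maps, validation-set threshold selection (ReLU-max
    rule and fixed thresholds), Dice/TPR/FPR overlap evaluation,
    threshold sweeps and lesion-size-stratified analysis. A speckled
    ultrasound-phantom generator with ground-truth lesion masks makes
    the whole pipeline runnable and testable without clinical data.
    Networks are trained with Adam under a cosine-annealed learning
    rate; convolution kernels are implemented in C++ via Rcpp.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    grDevices,
    jsonlite,
    png,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
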