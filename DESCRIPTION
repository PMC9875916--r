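Package: gancmlae
Title: Adversarially Regularized Multi-Loss Autoencoder for Individual Atrophy Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised anomaly detection for volumetric brain images built
    around a GAN-constrained multiple-loss autoencoder (GANCMLAE): a shared-weight
    convolutional encoder, decoder and Wasserstein latent critic trained only on
    normal-control images. The package provides a seeded synthetic phantom
    generator with ground-truth lesions, intensity normalization and axial
    slice/restack preprocessing, the combined adversarial + pixel + latent
    consistency training loop with ablation variants, SSIM/PSNR/MSE
    reconstruction metrics with per-subject slice averaging, and residual-map
    analysis: effective-atrophy thresholding, group frequency masks,
    cluster-extent filtering, a voxelwise t-test baseline, subject residual
    scores, z-scores and ROC/AUC discrimination.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    Rcpp,
    tibble,
    generics,
    ggplot2,
    RNifti,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
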