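Package: dbaae
Type: Package
Title: Denoising Single-Cell RNA-Seq Data with a Dynamic-Batching
    Adversarial Autoencoder
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Implements a dynamic-batching adversarial autoencoder (DB-AAE)
    for denoising dropout-affected single-cell RNA-seq count matrices. The
    adversarial autoencoder couples a fully connected encoder/decoder pair
    with a discriminator that contrasts the latent code of the current
    mini-batch against the latent code of the previous batch's
    reconstruction; a batch-size search sweeps a grid of candidate training
    batch sizes, records the minimum reconstruction loss and a held-out
    reconstruction accuracy per candidate, and retrains at the selected
    size. The package also provides a gamma-Poisson count simulator with
    logistic dropout for generating labelled benchmark data, dispersion
    based highly-variable-gene selection and z-score preprocessing with
    exact inverse transforms, and evaluation statistics (silhouette score
    over known labels and squared Pearson correlation between a pseudo-time
    ordering and annotated stages).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    cluster,
    optparse
Config/testthat/edition: 3
LinkingTo: Rcpp
RoxygenNote: 7.3.3
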