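Package: stainclust
Title: Information-Maximization Clustering of Multi-Stain Histopathology Patches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised clustering of co-registered multi-stain
    histopathology image patches with a convolutional autoencoder trained
    by regularized information maximization. Patches carrying five stain
    renditions (15 colour channels) are embedded into a shared latent
    space; a softmax classifier head is trained by maximizing the mutual
    information between patches and soft cluster assignments under
    reconstruction and affine-consistency penalties. The number of
    clusters is chosen by six internal cluster-validity indices with
    vote aggregation, and whole-slide images are rendered as per-tile
    cluster colormaps. Includes a synthetic multi-stain data generator,
    whole-slide tiling utilities, 2-D embedding of latent features, and
    an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    png,
    tiff,
    MASS,
    mclust,
    stats,
    utils,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr,
    optparse
Config/testthat/edition: 3
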