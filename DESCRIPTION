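Package: mitoscope
Title: Mitosis Detection in H&E Histopathology Tiles with Hybrid
    Swarm Feature Selection and a Skip-Connected Segmentation Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting mitotic figures in hematoxylin-and-eosin
    stained histopathology tiles. Provides optical-density stain separation
    and reference-based stain normalization, a fixed 150-slot bank of
    texture (local directional and local frequency patterns), shape and
    color descriptors, wrapper feature selection by a hybrid of the
    jellyfish-search and walrus optimization metaheuristics maximizing
    cross-validated F1, a VGG-16-style fully convolutional segmentation
    network with three 1x1-convolution skip connections trained with focal
    loss, an eleven-metric evaluation suite, and seeded generators of
    synthetic H&E-like tiles and labeled feature tables so the whole
    pipeline is exercisable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    jsonlite,
    yaml,
    png,
    tiff,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
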