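Package: eggcandler
Title: Candling-Image Classification of Duck Egg Hatching Status
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for classifying transmission (candling) images of
    incubated duck eggs into unfertilized, live-embryo and abnormal
    classes.  Provides a seeded synthetic candling-image generator for
    testing without proprietary image archives, an egg localisation
    chain (grayscale, median filter, Otsu thresholding with a manual
    offset, largest-component selection, scaled bounding-box crop), a
    from-scratch 34-layer residual network with pluggable channel and
    spatial attention (squeeze-and-excitation, coordinate attention,
    convolutional block attention), and a training and evaluation
    protocol reporting per-epoch stability statistics, confusion
    matrices and macro-averaged test metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    png,
    yaml,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
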