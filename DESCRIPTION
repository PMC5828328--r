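Package: vesselfcn
Title: Microvessel Segmentation in H&E Pathology Tiles with Fully
    Convolutional Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects microvessels in hematoxylin-and-eosin stained
    histopathology tiles with a fully convolutional network that fuses
    score maps from every pooling stage and upsamples the fused map only
    2x, alongside an FCN-8s baseline. Provides the layer primitives
    (convolution, max pooling, ReLU, learned deconvolution, softmax
    cross-entropy), a reproducible SGD training loop with step learning
    rate decay and validation-based stopping, pixel-level segmentation
    metrics (pixel accuracy, mean accuracy, mean IoU), object-level
    false-positive/false-negative counting of vessel components, and
    per-image microvessel-density features (total vessel area, fraction
    of tumor cells near vessels). A seeded synthetic H&E tile generator
    with ground-truth vessel masks, cell centroids and red-blood-cell
    confounders makes the whole pipeline testable without slide data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
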