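Package: noduleseg
Title: Pyramidal-Attention Encoder-Decoder Segmentation of Lung Nodules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds, trains and evaluates a lightweight encoder-decoder
    network for segmenting lung nodules in 64x64 CT patches. Encoder and
    decoder stages are inverted residual blocks (1x1 expansion, depth-wise
    convolution, squeeze-excitation, linear 1x1 projection) with the swish
    activation; the bridge is a feature-pyramid attention block built from
    7x7, 5x5 and 3x3 convolutions. Includes the depth-wise separable
    convolution cost model, Dice/IoU/sensitivity/precision overlap metrics,
    a synthetic nodule-phantom generator with pixel-exact ground-truth
    masks, horizontal-flip augmentation, dataset splitting, bicubic ROI
    crop-and-resize, and a reproducible Adam training loop. The numerical
    engine (convolution, batch normalization, bilinear resampling,
    backpropagation) is implemented in C++ via Rcpp/RcppArmadillo.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    graphics,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
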