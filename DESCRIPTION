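Package: pestpipe
Title: Field Insect Pest Classification Pipeline with Shape/Color Features and a BP-ANN
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying a single insect in a field photograph:
    hue-threshold segmentation with largest-connected-region denoising,
    a 13-dimensional feature vector (nine HSV color moments, eccentricity
    ratio, sphericity and two Hu invariant moments), a three-layer
    back-propagation neural network classifier with min-max normalization,
    and a framed stop-and-wait retransmission protocol for shipping image
    payloads over an unreliable byte channel. Includes a synthetic labeled
    image generator with pixel-exact ground-truth masks so every stage is
    testable without a field image collection.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    grDevices,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jpeg,
    tiff,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
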