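Package: graincountr
Title: Universal Crop-Grain Counting from Photographs on White Paper
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Counts touching crop grains (wheat, corn, mung bean, soybean,
    peanut, rapeseed) in photographs taken against a white-paper background.
    The pipeline binarizes the photo with Gaussian smoothing and Otsu
    thresholding, estimates each connected region's short axis from its
    morphological skeleton, erodes every region by a short-axis-proportional
    extent to break grain adhesions, and counts residual adhesion clusters
    with a concave corner-point formula (corners/2 - holes + 1) plus a
    skeleton length/angle rule that reroutes near-collinear overlaps to an
    average-area estimate. Includes a seeded synthetic scene generator with
    exact ground truth, accuracy metrics (correct/error ratio, volatility),
    a benchmark harness, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    stats,
    utils,
    grDevices,
    tibble,
    igraph,
    jsonlite,
    generics,
    yaml,
    png,
    jpeg,
    ggplot2
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
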