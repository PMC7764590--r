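Package: scaffseg
Title: Two-Stage Semantic Segmentation of Liver Scaffold Whole-Slide Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Segments hematoxylin-eosin stained whole-slide scans of
    decellularized liver scaffolds into background, intralobular and
    extralobular tissue. Stage one classifies every pixel of a 10 micrometre
    working-resolution bitmap with a Gaussian naive Bayes model over a
    nine-channel hand-crafted texture feature bank (RGB intensities, Gaussian
    smoothings, Sobel gradient magnitude and its smoothed and median-filtered
    responses), trained on sparse polygon annotations and fine-tuned per
    slide. Stage two distills the stage-one pseudo-labels into a miniature
    encoder-decoder convolutional network (UNet-Mini, about 123k parameters)
    with additive skip connections, so that new slides need no per-image
    annotation. Includes pyramidal slide input, polygon annotation parsing
    and rasterization, tiled inference with overlap stitching, a synthetic
    scaffold-scan simulator with exact ground truth for end-to-end testing,
    and pixel-accuracy evaluation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    withr,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
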