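Package: milts
Title: Teacher-Student Multiple Instance Learning for Slide-Level
    Expression Prediction from Tissue Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Weakly supervised prediction of a binary, expression-derived
    slide label from hematoxylin-and-eosin tissue images.  Slides are
    masked and tiled, continuous expression values are dichotomized at a
    percentile cutoff, and a teacher-student pair of convolutional
    instance scorers is trained under the multiple-instance constraint:
    each epoch the teacher ranks the tiles of every slide, the most
    class-representative tiles inherit the slide label, and the student
    minimizes a weighted cross-entropy on those pseudo-labeled tiles plus
    a consistency penalty tying its output to the teacher's on the
    remaining tiles; the teacher tracks the student by exponential moving
    average.  Tile features are fused into a slide token by self-attention
    and concatenated with trimmed summary statistics of the tile
    probabilities to train a slide-level classifier.  Includes ROC/Youden
    evaluation with bootstrap confidence intervals, probability heatmaps,
    matched-patch correlation against paired quantification grids, and a
    synthetic-slide generator with planted witness tiles so the full
    train/evaluate cycle runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    pROC
Config/testthat/edition: 3
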