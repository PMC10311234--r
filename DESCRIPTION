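Package: neuroqpi
Title: Simulated Training Data, Consensus Labeling, and Residual U-Net
    Segmentation for Quantitative Phase Images of Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building and evaluating semantic segmentation of
    quantitative phase imaging (QPI) micrographs of cultured neurons.
    Includes a stochastic two-dimensional neurite outgrowth simulator
    ("Petri dishes" of growing neurons), a pseudo-QPI renderer that turns
    neurite skeletons into smoothed phase-like images with ellipsoid cell
    bodies and synthetic speckle/debris noise plus automatically generated
    three-class labels, a geometric/photometric augmentation policy, a
    three-rater majority-vote consensus labeler with spatial tie-breaking,
    a compact residual U-Net trained with Dice loss (self-contained CNN
    engine, no external deep-learning framework), and post-processing
    utilities: connected-region size filtering with threshold sweeps,
    multi-granularity Dice evaluation, and cellular dry-mass quantification
    from phase maps.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    png,
    tiff,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
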