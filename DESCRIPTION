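Package: fimpipe
Title: Flow-Imaging Microscopy Processing for Automated Phytoplankton
    Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Image-processing pipeline for flow-imaging microscopy of
    freshwater phytoplankton: particle segmentation of widefield frames,
    morphometric feature extraction, random-forest filtering of
    out-of-focus particles, two-stage DBSCAN-based detection of stationary
    background particles recurring across consecutive frames, a micro-CNN
    closed-set classifier over particle crops, and classification with
    rejection (SoftMax thresholding, Monte-Carlo dropout, class-anchor
    clustering) for out-of-distribution particles. Includes a synthetic
    scene generator with full ground truth so the whole pipeline can be
    exercised and calibrated without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    EBImage,
    randomForest,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
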