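Package: abct
Title: Automated Counting and Morphometry of Asbestos Bodies in X-Ray
    Micro-Tomography Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects, counts, and measures asbestos bodies in reconstructed
    X-ray micro-tomography volumes of lung tissue. Provides grey-level
    segmentation, 3D connected-component labelling, shape-descriptor
    filtering (size, sphericity, solidity, aspect ratio), fibre
    morphometry (principal-extent length and width, log-normal length
    statistics), and the stereological conversion of counts per embedded
    tissue volume to asbestos bodies per gram of dry lung, including the
    orientation correction factor for thin-section counting. A synthetic
    phantom generator with exact per-fibre ground truth makes every stage
    of the pipeline testable without real tomograms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
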