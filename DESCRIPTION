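Package: shgfib
Title: Collagen Fibrosis Quantification from Second-Harmonic Generation Microscopy Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for second-harmonic generation (SHG) microscopy
    images of liver tissue: sliding-window statistical feature extraction from
    photon-count images, random-forest feature ranking, from-scratch K-means
    label validation, a single-sigmoid-neuron fibrosis classifier with
    stratified k-fold cross-validation, Hough-transform collagen fiber
    orientation analysis with circular dispersion statistics, and per-cohort
    fibrosis-percentage summaries. Includes a synthetic SHG phantom generator
    so the full pipeline is testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    randomForest,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    ranger,
    jsonlite
Config/testthat/edition: 3
LinkingTo: Rcpp
RoxygenNote: 7.3.3
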