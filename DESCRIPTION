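Package: eitsep
Title: Separation of Cardiac and Pulmonary Signals in Electrical
    Impedance Tomography by a Dual-Decoder U-Net
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation-to-segmentation pipeline for difference electrical
    impedance tomography (EIT) of the thorax. Generates finite-element
    thorax phantoms with lung and heart inclusions, solves the 2D EIT
    forward problem for a 16-electrode adjacent-pair protocol, trains a
    GREIT-style linear reconstruction matrix, and fits a semi-Siamese
    U-Net (one shared encoder, two task decoders) with a multi-weighted
    binary cross-entropy loss to separate heart-related from lung-related
    impedance images. Includes a classical single-decoder U-Net baseline,
    Dice/MAE evaluation, the weight-ratio grid search, and an optional
    adapter for the public EIDORS human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    stats,
    graphics,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    MASS,
    png,
    optparse
Config/testthat/edition: 3
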