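Package: strobomech
Title: Stroboscopic Optical Mechanotyping of Adherent Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of acoustically sheared adherent cells imaged
    stroboscopically: homodyne (lock-in) detection of digital image
    correlation and particle tracking displacement fields yields per-pixel
    complex dynamic shear modulus maps (storage modulus G' and loss modulus
    G''), together with population statistics, distance-to-edge profiles and
    an error budget. A synthetic-experiment generator renders image stacks
    with known ground-truth moduli so the whole chain is verifiable by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    MASS,
    EBImage,
    tiff,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
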