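Package: ionbeamqc
Title: Radiobiological Quality Control for Clinical Ion Beams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for radiobiological quality control of clinical particle
    beams: clonogenic survival curve fitting (linear-quadratic and linear
    models) with relative biological effectiveness (RBE) at an isosurvival
    level, Poisson statistics of intranuclear ion hits from particle fluence
    and nuclear cross-sectional areas, read-out of fluorescent nuclear track
    detector (FNTD) images with primary/fragment classification, nucleus
    segmentation and gamma-H2AX focus quantification with repair kinetics,
    and registration of track spots to DNA-damage foci by a global
    translation. A synthetic-data module generates every input with known
    ground truth so the whole pipeline is testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
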