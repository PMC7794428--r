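Package: coralcasa
Title: Computer-Assisted Sperm Analysis for Coral Sperm Motility and
    Concentration
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An open computer-assisted sperm analysis (CASA) pipeline for
    coral sperm: detection of sperm heads in darkfield-style video fields,
    maximum-displacement track linking, curvilinear/average-path/straight-line
    velocity kinematics, four-class motility binning (static, slow, motile,
    progressive), concentration estimation from chamber geometry, capture
    quality-control flags, cross-instrument concentration formulas
    (haemocytometer, flow cytometer), and egg-to-motile-sperm fertilisation
    dose planning.  Includes a ground-truthed synthetic capture simulator so
    every stage is testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
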