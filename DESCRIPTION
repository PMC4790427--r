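Package: bcmfa
Title: Bonded-Cumomer Metabolic Flux Analysis for Dynamic 13C MRS of Brain
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward simulation and flux estimation for compartmental
    neuronal-glial models of brain energy metabolism observed by dynamic
    in vivo 13C magnetic resonance spectroscopy. Implements the bonded
    cumomer formalism for propagating positional 13C label and 13C-13C
    multiplet fine structure of glutamate and glutamine through an
    atom-mapped two-compartment metabolic network during
    [1,6-13C2]glucose infusion, together with weighted
    Levenberg-Marquardt flux estimation, Monte-Carlo uncertainty and
    correlation analysis, and sensitivity scans of individual fluxes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    minpack.lm,
    MASS,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
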