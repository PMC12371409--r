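Package: cfecrosstalk
Title: Kinetic Modelling of Plasmid Crosstalk in Cell-Free Expression Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mass-action kinetic modelling of lysate-based cell-free
    transcription-translation (TXTL) reactions with explicit competition for
    RNA polymerases, ribosomes, and ribonucleases, together with a lumped
    toxin mechanism that terminates expression at high template loads.
    Provides a network compiler for transcription-unit registries, stiff ODE
    simulation under bolus plasmid/mRNA dosing, enumeration of
    promoter-by-concentration-by-combination experiment grids, crosstalk
    ratios, surrogate terms encoding qualitative dose-response trends,
    log-space Latin hypercube parameter screening with biological filter
    heuristics, least-squares time-course fitting, surrogate-objective
    optimization, and rank-based global sensitivity analysis (PRCC and
    Spearman).
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    lhs,
    minpack.lm,
    Rcpp,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
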