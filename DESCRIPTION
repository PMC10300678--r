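Package: squirmers
Title: Hydrodynamics of Spherical Squirmers Near Rigid Walls
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Models the low-Reynolds-number hydrodynamics of spherical
    squirmer microswimmers sedimenting towards rigid no-slip walls.
    Provides far-field singularity representations (stresslet and source
    dipole) with exact wall image systems, equilibrium height and
    orientation analysis for a single swimmer under gravity, symmetric
    two-swimmer encounter dynamics, near-field lubrication torques, and
    orientation-stability analysis (dynamic simulation and closed-form
    criteria) for circular, filled and partial clusters of squirmers in
    the bulk, above one wall, and confined between two walls.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    utils,
    tibble,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
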