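Package: brushflow
Title: Electro-Osmotic Flow Screening by Grafted Polymer Coatings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how grafted polymer coatings screen
    electro-osmotic flow in nanoslits. Solves the one-dimensional
    Navier-Stokes-Brinkman equation for the flow profile across a slit,
    infers the effective Stokes radius of polymer beads by velocity-profile
    matching and by Stokes-law extraction from drag tables, computes
    coating-structure statistics (non-normalized radial distribution
    functions, orientation distributions, exposed far-bead counts, gyration
    radii and their scaling), and evaluates an additive far-bead
    hydrodynamic-shielding model. Includes generators for synthetic coating
    configurations, Gouy-Chapman double layers, self-avoiding-walk
    ensembles, and forward-solved velocity profiles for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
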