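Package: lungchip
Title: Nanoparticle Transport in a Gas-Liquid Dual-Channel Lung-on-a-Chip
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the transport, deposition and translocation of inhaled
    nanoparticles (10-900 nm) in a two-channel microfluidic lung-on-a-chip: an
    air channel and a cell-culture media channel separated by a thin porous
    membrane. Solves the steady incompressible creeping-flow field in the
    coupled channels on a staggered grid, then traces particles with an
    overdamped (or inertial) Langevin integrator under Stokes drag, Brownian
    forcing and buoyant weight, with a sticky membrane-top substrate and
    pass-through pores. Computes deposition and transfer rates, deposit and
    outlet distribution statistics, band-averaged concentrations and
    concentration-time curves with Gaussian peak fits, and provides parametric
    sweep drivers and verification suites.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
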