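Package: capnet
Title: Cerebral Capillary Network Blood Flow and Drug Transport Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds calibrated cubic-lattice models of the cerebral capillary
    bed, solves pressure-driven laminar blood flow on them (Hagen-Poiseuille
    conductances with diameter-dependent blood viscosity, Kirchhoff nodal
    balance), and computes steady-state concentrations of a carrier-transported
    drug (such as L-Dopa crossing the blood-brain barrier via the LAT1
    transporter) in blood and brain tissue under saturable Michaelis-Menten
    kinetics. Provides a coarse-to-fine grid scaling analysis with a
    variance-weighted saturating fit of tissue uptake against vessel exchange
    area, power-law extrapolation of network perfusion to capillary-scale
    radii, and tissue:plasma partition coefficients. Vessel graphs round-trip
    through GraphML, JSON and edge-list CSV.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    deSolve,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
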