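Package: aplg
Title: Active-Passive Lattice Gas: Exact Hydrodynamics, Phase Coexistence and Traveling Waves
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Toolkit for a two-dimensional active-passive lattice gas (APLG), an
    exclusion process mixing self-propelled (left/right oriented) and passive
    diffusive particles. Provides exact continuous-time (Gillespie) lattice
    simulation, deterministic integration of the exact hydrodynamic limit
    equations in one space dimension, linear stability analysis of homogeneous
    states (dispersion relations, spinodal curves, Bogdanov-Takens points),
    liquid-vapor phase coexistence via a generalized common-tangent
    construction (binodals, tie lines, interface profiles), traveling-wave
    solvers at finite system size and in the matched-asymptotics large-size
    limit, and automated classification of long-time states into homogeneous,
    phase-separated, traveling and counter-propagating.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    pracma,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
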