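Package: burstwave
Title: Bursting Neuron Dynamics, Square-Root Timing Laws, and Metachronal
    Waves in Inhibitory Chains
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and bifurcation analysis of a four-dimensional
    conductance-based bursting neuron whose slow potassium and
    hyperpolarization-activated gates are steered by two half-activation
    voltages.  The package maps regimes of activity (silence, tonic
    spiking, bursting, bistability) over this two-parameter plane, locates
    the saddle-node bifurcations for equilibria and for periodic orbits
    and their codimension-2 intersection, fits the inverse-square-root
    temporal laws that govern burst duration, interburst interval and
    pulse-triggered responses near those bifurcations, performs slow-fast
    decomposition with orbit averaging, and assembles five-cell inhibitory
    chains that produce duty-cycle-preserving metachronal waves.  Traces,
    spike tables, regime grids and fit results are returned as tibbles;
    fitted law objects support tidy(), glance() and autoplot().
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    jsonlite,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
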