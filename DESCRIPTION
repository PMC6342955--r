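Package: crowdperc
Title: Tracer Diffusion and Pore-Scale Transition Rates in Crowded
    Two-Dimensional Media
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for hard-disc tracer diffusion
    in quenched two-dimensional random obstacle matrices (the 2D Lorentz
    model with excluded volume). Generates random sequential adsorption
    obstacle configurations, tessellates the void space into a periodic
    Delaunay pore network, locates the continuum percolation threshold by
    finite-size scaling, evolves tracers with dynamic Monte Carlo under
    geometric channel-passability rules, extracts the dynamic conductivity
    exponent from the vanishing of the diffusion coefficient near threshold,
    and compares transition-state-theory channel rates with numerically
    measured mean first-passage rates to probe the breakdown of the local
    equilibrium approximation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
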