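Package: gradewalk
Title: Potential-Energy Model of Human Gradient-Walking Energetics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Parametric model of the per-step mechanical cost of walking on
    a gradient. Computes the centre-of-mass vertical oscillation from leg
    length and the dimensionless step parameter k (step length = l/k), the
    potential-energy cost of raising the body against a gradient, and a
    piecewise braking-adjusted cost that credits negative (eccentric) work
    at a configurable efficiency factor. Provides closed-form, exact-root
    and numeric-argmin solvers for the energy-minimising negative gradient
    as a function of k, the algebraic inverse recommending a step length
    for a given downhill gradient, order-of-magnitude checks of kinetic
    versus potential per-step energy, parameter-sweep tables with CSV/JSON
    round-tripping, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
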