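Package: fasciclesim
Title: Compartmental Simulation of Local Anesthetic Kinetics in a Nerve Fascicle
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a two-dimensional hexagonal-lattice model of a peripheral
    nerve fascicle cross-section (nerve fiber, extracellular fluid and
    capillary compartments), assembles the linear compartmental ODE system for
    local anesthetic diffusion, membrane exchange and perfusion-limited
    capillary clearance, integrates bolus filling and washout (voiding)
    phases, and computes onset time and duration of action for lidocaine and
    bupivacaine under physiological and acidotic tissue pH.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    deSolve,
    methods,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
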