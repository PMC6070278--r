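Package: protoflux
Title: Evolutionary Dynamics of Protocells with Metabolic Fitness
Version: 1.0.0
Authors@R:
    person("Protoflux", "Developers", email = "protoflux@example.org",
           role = c("aut", "cre"))
Description: Models a population of protocells (vesicles encapsulating
    replicating catalytic sequences) whose fitness is the steady-state
    output flux of a small irreversible Michaelis-Menten reaction network.
    Provides piecewise-linear and finite-permeability flux evaluation for
    feed-forward catalysed networks, the Wright-Fisher protocell life-cycle
    (multinomial development with mutation to a defective type, followed by
    hypergeometric assortment at fission), an exact infinite-population
    stationary solver by Perron-Frobenius power iteration, a finite-population
    agent-based simulator, summary observables (coexistence fraction, mean
    flux, defective-type frequency, ternary projections), built-in network
    fixtures, and a configuration-driven command line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
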