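Package: metabogame
Title: Evolutionary Game Dynamics of Tumour Metabolic Symbiosis
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models the glucose/lactate division of labour between hypoxic and
    oxygenated tumour cell populations as a two-player, two-action evolutionary
    game, and couples the populations through replicator dynamics with a
    Boltzmann (logit) exploration term representing genomic instability.
    Provides construction of the symbiosis payoff matrices from ATP yields,
    pure Nash enumeration, numerical integration of the coupled dynamics,
    multi-start location and stability classification of the Boltzmann
    self-consistent fixed points, one-parameter bifurcation sweeps with fold
    refinement, basin-of-attraction maps, the two-parameter exploration-rate
    phase diagram with metabolic-coupling classification, and quasi-static
    therapy-path tracking with hysteresis detection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    graphics,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
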