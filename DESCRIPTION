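Package: sarcomech
Title: Half-Sarcomere Force Generation with Cross-Bridge and Titin Mechanics
Version: 0.1.0
Authors@R: person("Sarcomech", "Developers", email = "sarcomech@example.org",
    role = c("aut", "cre"))
Description: Simulates force generation in a single half sarcomere by coupling
    a three-state cross-bridge distribution model (advection-reaction PDE over
    cross-bridge strain) to a stochastic serial-compartment model of the titin
    filament (worm-like-chain immunoglobulin domains, an extensible worm-like
    chain PEVK segment, Monte-Carlo force-dependent domain unfolding) with
    activation-triggered titin-actin binding. Reproduces history-dependent
    muscle phenomena such as residual force enhancement, force depression,
    passive force enhancement and force generation beyond actin-myosin
    filament overlap. Includes passive hysteresis calibration by
    Levenberg-Marquardt fitting, a synthetic hysteresis generator, protocol
    definitions for canonical stretch-shorten experiments, CSV/JSON
    input-output and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
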