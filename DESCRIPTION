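Package: delaysim
Title: Exact Stochastic Simulation of Reaction Networks with Time Delays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact stochastic simulation of well-mixed biochemical reaction
    networks, with first-class support for delayed (non-Markovian) reactions.
    Implements the Gillespie direct, first-reaction and modified next reaction
    methods, and their three delay-capable counterparts (rejection, direct and
    modified-next-reaction with a pending-completion queue), behind one driver.
    Ships constructors for classical gene-expression models (bursty
    transcription, three-state refractory promoter, RNA velocity two-phase
    kinetics) and a four-gene lung-cancer adeno-to-squamous transition network,
    a concentration-to-molecule model conversion, quasi-potential landscape
    estimation from simulated ensembles, deterministic attractor counting, and
    a JSON model-configuration interface with a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    compiler,
    deSolve,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
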