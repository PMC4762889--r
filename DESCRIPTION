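Package: awenh
Title: Climate-Driven Five-Pool Soil Carbon Modelling and Aggregation Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A Yasso07-style litter decomposition and soil carbon model with
    five chemical pools (acid-hydrolyzeable, water-soluble, ethanol-soluble,
    non-soluble and humus), climate- and woody-size-modified first-order
    kinetics, exact matrix-exponential annual stepping and analytic steady
    states.  Around the core the package provides forest-inventory litter
    bookkeeping from biomass components and turnover rates, steady-state
    spin-up initialization with historical litter back-casting, spatial and
    temporal climate-input aggregation schemes, a factorial simulation
    experiment quantifying aggregation effects on soil carbon stocks and
    stock changes, and a synthetic national-forest-inventory landscape
    generator so the whole pipeline runs without restricted data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
RoxygenNote: 7.3.3
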