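Package: ferrocycle
Title: Agent-Based Simulation of Microbial Iron Redox Cycling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic agent-based model of coupled iron cycling between
    ferric-iron-reducing bacteria (FeRB, Shewanella-type) and ferrous-iron-
    oxidizing bacteria (FeOB, Sideroxydans-type) on a three-dimensional
    toroidal lattice. Submodels cover diffusive and run-and-tumble movement,
    mineral adhesion and detachment, contact, nanoparticle and electron-shuttle
    reduction, biotic oxidation with two encrustation-prevention strategies,
    first-order abiotic oxidation, ferrous-iron phase equilibration,
    nanoparticle aggregation, dissociation and loss, and secondary-mineral
    aging. Includes scenario presets (pH, modes of action, oxic/anoxic
    cycling schedules), replicate experiment runners, and variance-based
    global sensitivity analysis (Saltelli sampling, first-, second- and
    total-order Sobol indices with bootstrap confidence intervals).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    lhs
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
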