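Package: fluorokin
Title: Microkinetic Feasibility and Barrier Regression for Copper-Catalysed
    Fluoroalcohol Synthesis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-side computational chain for assessing Cu(I)/NHC-catalysed
    additions of alkylboranes to symmetric ketones en route to fluoroalcohols.
    Implements standard-state Gibbs thermochemistry (1 M reference state),
    assembly of catalytic-cycle free-energy profiles with extraction of the
    overall activation barrier and its determining transition state,
    Eyring transition-state-theory rate constants fed into stiff mass-action
    microkinetic simulations (including a fixed-transition-state barrier
    sweep and a 16-hour feasibility-limit analysis), conceptual-DFT global
    reactivity descriptors, and a cross-validated two-descriptor multilinear
    regression estimator of activation barriers. A seeded synthetic-system
    generator emulating the substrate-library design makes every pipeline
    stage testable without electronic-structure calculations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
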