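Package: fotsim
Title: Fractional-Order Tumor-Immune Treatment Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates breast-cancer treatment with a 15-compartment
    tumor/immune/microenvironment/pharmacokinetic ordinary differential
    equation model whose derivatives are scaled by a time-dependent
    fractional-order memory factor. Provides dosing schedulers (cyclic,
    continuous, response-adaptive, hyperthermia sessions), Hill-equation
    pharmacodynamics, virtual patient profiles, five treatment protocols,
    outcome metrics (tumor reduction, resistance fraction, composite
    efficacy), a comparative fractional-order x profile x protocol
    experiment grid, fractional versus integer-order comparisons, and a
    normalized local sensitivity-analysis engine with parameter
    classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    parallel,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
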