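Package: rootsim
Title: Coupled Mechano-Biochemical Simulation of Root Meristem Growth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates anisotropic growth of the Arabidopsis root meristem on a
    2D cellular mesh by coupling Position-Based Dynamics (PBD) tissue mechanics
    to polar auxin transport. Cells are triangulated polygons whose walls carry
    apoplastic auxin and membrane-bound carrier pools; PIN efflux carriers
    polarize through either an auxin-flux feedback or a regulator-polarizer
    mechanism, gated by a strain-driven anisotropy factor and cell geometry.
    Auxin relaxes wall stiffness in a biphasic manner, driving turgor-based
    growth and area-triggered, cell-type-specific divisions. Includes a
    synthetic heart-stage root template generator, mesh JSON I/O, a scenario
    driver with in-silico perturbations (ablations, knockdowns, auxin pulses),
    parameter sweeps and output metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
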