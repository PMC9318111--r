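Package: findose
Title: Finite-Dose Percutaneous Absorption Prediction from Membrane
    Permeation Parameters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts percutaneous absorption of chemicals applied to skin
    as small ("in-use") aqueous doses, accounting for solvent evaporation.
    Implements a two-phase compartment model based on Fick's first law of
    diffusion: before the vehicle has evaporated the chemical depletes from
    a pooled surface + stratum-corneum compartment; afterwards only the
    stratum-corneum depot keeps clearing into deeper layers. Permeation
    parameters (steady-state flux, lag time, permeability coefficient Kp,
    diffusion coefficient D and partition coefficient K) are estimated from
    infinite-dose Franz-cell permeation profiles by the classical lag-time
    method, with an optional receiver-sampling withdrawal correction. The
    package also estimates the complete-evaporation time from applied-
    solution weight series, generates synthetic Franz-cell studies with
    known ground truth, and evaluates predicted versus observed absorption
    ratios (Pearson correlation, regression slope, factor-2 agreement).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
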