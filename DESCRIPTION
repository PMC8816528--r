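Package: nephrosim
Title: Whole-Body PBPK Simulation of Renal Drug Disposition and Crystalluria Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Physiologically based pharmacokinetic (PBPK) simulation of drugs
    cleared by the kidney, with a mechanistic nephron model that tracks drug
    concentration in the tubular filtrate from the glomerulus down to the
    medullary collecting duct. Includes virtual populations for healthy adults,
    geriatric subjects, and chronic kidney disease under alternative hypotheses
    about the decline of tubular secretion (proximal tubule cellularity,
    transporter abundance, uremic inhibition), a virtual-trial engine,
    noncompartmental analysis, crystalluria risk assessment against an aqueous
    solubility window, prediction-error metrics (AFE, GMFE, RMSE), and a
    synthetic sparse clinical-data generator for parameter-recovery studies.
    Shipped with a ganciclovir/valganciclovir parameterisation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
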