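Package: brainpbpk
Title: Pediatric Whole-Body PBPK Simulation of Plasma and Cerebrospinal Fluid Drug Concentrations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A whole-body physiologically-based pharmacokinetic (PBPK) simulator with a
    four-compartment brain and cerebrospinal-fluid (CSF) sub-model (brain blood, brain mass,
    cranial CSF, spinal CSF) for predicting plasma and CSF concentration-time profiles from
    preterm neonates to adults. Includes age-dependent physiology with log-normal
    inter-individual variability, composition-based tissue partitioning, virtual-population
    Monte-Carlo simulation, non-compartmental analysis and visual-predictive-check tables,
    CSF-production sensitivity analysis, and empirical estimation of blood-brain-barrier
    permeability from meningitis concentration data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
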