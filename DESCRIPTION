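Package: entocost
Title: Decision-Tree Cost Comparison for Entomological Surveillance
    Laboratory Workflows
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deterministic decision-tree costing engine for comparing
    laboratory workflows in mosquito (vector) surveillance programmes.
    Builds per-sample, per-assay cost profiles from item-level reagent
    and consumable prices (micro-costing), evaluates probability-weighted
    workflow trees over a sample cohort to obtain expected time,
    materials, labour and direct-cost totals, and compares alternative
    workflows with absolute and percentage savings. Ships the current
    (PCR/ELISA), proposed (MALDI-TOF MS) and ideal (MALDI-only) workflow
    models of the Kenyan national malaria control programme case study,
    plus one-way and probabilistic sensitivity analysis and a stochastic
    cohort simulator used as an independent check on the deterministic
    engine.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
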