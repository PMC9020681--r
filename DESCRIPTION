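Package: noacce
Title: Markov Cohort Cost-Effectiveness Model of Oral Anticoagulants in
    Non-Valvular Atrial Fibrillation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A Markov cohort state-transition model comparing the non-vitamin-K
    oral anticoagulants rivaroxaban, dabigatran and apixaban, each against
    vitamin K antagonist therapy, for stroke prevention in non-valvular atrial
    fibrillation from the Spanish National Health System perspective. The model
    runs 3-month cycles over a lifetime horizon with time-varying treatment
    discontinuation, age-adjusted stroke risk, life-table background mortality
    and 3 percent annual discounting. Includes deterministic (tornado) and
    probabilistic sensitivity analyses with cost-effectiveness acceptability
    curves, published scenario analyses, a synthetic Gompertz-Makeham life-table
    generator, and a patient-level microsimulation used to validate the cohort
    engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
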