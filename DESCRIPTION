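Package: ebloss
Title: Dynamic Energy-Balance Modelling of Weight Loss on Very
    Low-Energy Diets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates body-weight trajectories during energy restriction
    with an ordinary differential equation that accounts for obligatory
    reductions in energy expenditure (loss of metabolically active
    fat-free mass) and adaptive thermogenesis (the underfeeding-associated
    fall in resting energy expenditure beyond what tissue loss explains).
    Provides baseline body-composition prediction from weight and sex,
    Cunningham and Mifflin resting-energy-expenditure equations,
    constant and stepped energy-intake schedules, the static 3500-kcal
    comparator rule, agreement statistics (per-subject mean error and
    Bland-Altman limits of agreement) for observed-versus-predicted
    weekly weights, and a synthetic-cohort generator that emulates a
    commercial very-low-energy total-diet-replacement programme,
    including early glycogen-water loss and late compliance drift.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
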