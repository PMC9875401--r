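Package: icmcea
Title: Cost-Effectiveness of Insertable Cardiac Monitors for Atrial
    Fibrillation Detection in a High-Risk US Population
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lifetime Markov cohort model comparing insertable cardiac
    monitors (ICM) against standard-of-care intermittent monitoring (SoC)
    for detecting atrial fibrillation in patients at high stroke risk
    (CHADS2 >= 2), from a US payer perspective. Detected AF triggers oral
    anticoagulation, which trades ischemic-stroke reduction against
    bleeding risk. The package provides a typed parameter registry with
    scenario overrides, detection-curve extrapolation (logarithmic,
    linear, none), stratified per-cycle risk conversion, a factored-state
    cohort engine with discounted cost/QALY/life-year accumulation,
    incremental cost-effectiveness outputs (ICER, NNT, category
    breakdowns), probabilistic and one-way deterministic sensitivity
    analysis with cost-effectiveness acceptability curves, a scenario and
    subgroup grid, and synthetic-data generators (life tables, trial-like
    detection times, randomized parameter bundles) plus a patient-level
    microsimulation oracle used to validate the cohort algebra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
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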