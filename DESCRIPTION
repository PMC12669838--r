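Package: diveO2
Title: Blood Oxygen Transport and Dive Oxygen Store Budgets in Diving Birds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for modelling blood oxygen transport across the dive cycle
    of deep-diving birds such as the emperor penguin. Provides pH-dependent
    oxygen-hemoglobin dissociation curves (Hill form) with a Bohr-shift model
    interpolated from P50 anchor points, conversion of dive PO2/depth time
    series into hemoglobin-saturation profiles, blood and total-body oxygen
    store accounting (content, compartment stores, depletion rates, diving
    metabolic rate contributions), post-dive saturation recovery-time
    extraction, random-intercept regressions of blood pH on PCO2 and lactate
    used to bound blood pH, and a seeded synthetic-data generator for blood
    panels and dive records.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
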