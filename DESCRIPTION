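Package: afcea
Title: Markov Cohort Cost-Effectiveness Model of mHealth-Based Integrated
    Care for Atrial Fibrillation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A monthly-cycle Markov cohort model comparing mobile-health
    (mHealth) based integrated care, following the Atrial fibrillation
    Better Care (ABC) pathway, against usual care for patients with atrial
    fibrillation in China. Tracks ischemic stroke, intracranial
    hemorrhage and gastrointestinal bleeding with severity escalation and
    an anticoagulant-to-aspirin switch, accrues discounted costs and
    quality-adjusted life years over a 30-year horizon, and provides
    model validation against trial event rates, one-way (tornado,
    threshold) sensitivity analysis, and probabilistic sensitivity
    analysis with cost-effectiveness acceptability curves. Ships the full
    base-case parameter set as a machine-readable fixture and a synthetic
    scenario generator for property testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
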