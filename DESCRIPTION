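Package: adhereRx
Title: Dose-Window Medication Adherence Scoring, Reminder Escalation,
    Home Blood Pressure Summaries, and Mixed Repeated-Measures Trial
    Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Pipeline for electronic medication event monitoring (MEMS)
    trials in transplant hypertension. Matches pill-tray compartment
    openings to a prescribed dosing schedule and computes a windowed
    adherence score (full credit within +/-90 minutes, half credit
    within +/-180 minutes), classifies screening eligibility, generates
    reminder-escalation timelines and blood-pressure safety alerts,
    reduces three-reading resting blood pressure sessions, stages
    readings into JNC 7 hypertension categories, builds weekly provider
    reports, and analyses two-arm by four-timepoint trials with a mixed
    repeated-measures ANOVA (partial eta squared, Bonferroni-adjusted
    confidence intervals). A seeded synthetic-data generator emulates
    per-dose taking behaviour and the adherence-to-blood-pressure
    coupling so every stage is testable without device logs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
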