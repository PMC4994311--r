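Package: rxalert
Title: Trigger-Based Alerts and Silent Surveillance for Controlled-Substance Prescribing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A clinical decision-support engine for opioid and benzodiazepine
    prescribing. Implements a five-trigger risk rule (early refill,
    repeated emergency/urgent-care visits with onsite opioid treatment,
    recent controlled-substance prescription history, prior overdose
    presentation, and positive toxicology screens) evaluated at every
    prescription initiation, a silent-surveillance mode that logs
    would-have-fired alerts without interrupting prescribers, aggregate
    surveillance reporting over prescribing encounters, and a
    threshold-tuning sweep that quantifies alert burden against additional
    at-risk patients captured. Ships a seeded synthetic EMR cohort
    simulator so the whole pipeline is exercisable without real patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lubridate,
    readr,
    rlang,
    stats,
    tibble,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
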