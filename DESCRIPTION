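Package: emstt
Title: Emergency Medical Services Trigger Tool for Adverse Event Surveillance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Rule-based screening of prehospital patient care records for
    eight adverse-event trigger items, with dual-reviewer harm
    classification (modified NCC MERP and an EMS severity rating index),
    inter-rater reliability statistics (percent agreement and Cohen's
    kappa), biweekly review sampling with exclusion handling, outcome
    measures per 10,000 patient encounters, and U-chart statistical
    process control with Nelson-rule special-cause detection. Includes a
    seeded synthetic cohort generator with known ground-truth labels so
    the full pipeline can be exercised and validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
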