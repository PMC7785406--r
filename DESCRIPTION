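Package: hfsymptoms
Title: Symptom-Based Prediction of Imminent Heart Failure Hospitalization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing twice-weekly heart-failure telemonitoring
    data: objective vitals (blood pressure, heart rate, weight, B-type
    natriuretic peptide) and four respiratory symptoms scored on a 5-point
    Likert scale (dyspnea, orthopnea, bendopnea, paroxysmal nocturnal
    dyspnea). Implements pre-admission eligibility windows with windowed
    mean/SD/slope and median/range summaries, random-day resampling for
    Youden-optimal per-symptom cutoff selection, evaluation of
    multi-symptom decision rules under single-day and two-consecutive-visit
    temporal modes, and a seeded synthetic longitudinal cohort generator
    for end-to-end testing of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
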