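Package: oxiweek
Title: Week-Long Continuous Pulse-Oximetry Analysis for COPD Home Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing week-long continuous 1 Hz pulse-oximetry (SpO2)
    recordings paired with 1/min actigraphy in patients with chronic obstructive
    pulmonary disease. Implements artifact cleaning of SpO2 streams (error-sentinel
    handling, exclusion of short and deviating blocks between errors, 20-second
    median down-sampling, linear gap interpolation), actigraphy-based segmentation
    into nights and days with activity-level partitioning (rest/LIPA/MVPA by MET
    cut-points), per-period feature extraction (mean SpO2, SpO2 SD, CT90, data
    quality, sleep metrics), weekly aggregation, nocturnal-desaturator
    classification, cohort-level statistics, and a synthetic-data generator with
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
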