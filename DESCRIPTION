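Package: phenocap
Title: Digital Phenotyping of Smartphone Sensor and Survey Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis pipeline for smartphone digital
    phenotyping studies of college-student cohorts. Generates seeded
    synthetic cohorts with ground-truth behavior (GPS fixes, accelerometer
    epochs, screen-state events, psychometric survey responses, and a
    recruitment/attrition funnel with a perceived-stress eligibility gate);
    extracts the passive features home time (via weighted significant-location
    clustering), sleep duration (minimal-activity sleep-window estimation in
    the 18:00-10:00 overnight interval), and screen duration; scores and
    normalizes a PHQ-9/GAD-7/PSS/UCLA/PQ-16/PSQI/D-WAI battery; and compares
    perceived COVID-19 exposure groups with one-sided pooled-variance
    two-sample t-tests, including reconstruction of published group
    comparison tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    geosphere,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
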