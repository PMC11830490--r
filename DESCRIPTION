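Package: gpsmobility
Title: Smartphone GPS Mobility Features and Lagged Quality-of-Life Correlation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A digital-phenotyping analysis pipeline for passively collected
    smartphone GPS traces. Extracts four daily mobility features (total
    distance travelled, time spent at home, transition time, and number of
    significant locations), applies data-quality filtering based on valid
    GPS hours per day and valid days per week, aggregates features to
    assessment-anchored weeks, and estimates time-lagged repeated-measures
    correlations between weekly mobility and patient-reported quality-of-life
    T-scores, with cluster-bootstrap confidence intervals. Includes a
    synthetic-cohort generator with analytically known ground truth so the
    full pipeline can be validated without access to sensitive location data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
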