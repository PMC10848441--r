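Package: camsnap
Title: Occupancy and Camera-Trap Distance Sampling for Camera-Trap Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for estimating site occupancy and population density from
    camera-trap records without individual identification. Implements
    single-season occupancy estimation by direct maximum likelihood on daily
    detection histories, and camera-trap distance sampling (CTDS): point-transect
    detection-function fitting (half-normal and hazard-rate keys with cosine
    adjustments), AIC model averaging of detection probability, activity-level
    (availability) estimation by circular kernel density, encounter-rate variance,
    and delta-method propagation of coefficients of variation. Reads and writes
    Camtrap DP and Darwin Core Archive tables, groups images into occurrence
    sequences, and ships a synthetic-scenario generator with known truth so every
    stage of the pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    pracma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
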