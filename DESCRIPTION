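Package: streetcount
Title: Predicting City-Level Travel Patterns from Street-Imagery Road-User Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating city-level travel patterns (commute mode
    shares and past-month walking and cycling) from manual road-user counts in
    archived street imagery. Implements staged sampling of street-network
    locations with year-prioritised panorama selection, aggregation of
    image-level count bins into city-level presence counts with bootstrap
    uncertainty, beta regression with a logit mean link, Huber M-estimation,
    ordinary least squares, leave-one-out cross-validation with PRESS-guided
    backward variable selection, and a cyclist gender-split analysis. A seeded
    synthetic-city generator with known ground truth makes the whole pipeline
    testable without any imagery download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    MASS,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
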