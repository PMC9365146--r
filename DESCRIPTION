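Package: gpsafit
Title: Group Problem-Solving Ability: Model, Surfaces and Annealed Fitting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-form model of group problem-solving ability (GPSA) in
    collective-governance settings, built from representational diversity,
    representational gaps, and their moderation by group general
    intelligence (g), theory of mind (ToM) and cognitive-tool parameters
    (alpha, beta). Provides grid evaluation of the GPSA response surface,
    min-max preprocessing of raw indicator tables into model-scale
    observation sets, fitting of the model by multi-restart dual simulated
    annealing (global annealing plus bounded local polish), pooled and
    per-unit fit summaries, ordered prediction checks across governance
    levels, and a synthetic-data generator for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
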