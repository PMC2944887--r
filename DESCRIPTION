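Package: phenogdd
Title: Growing Degree-Day Phenology and Resurvey Analysis
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying insect phenological change from historical
    resurveys using growing degree-days (GDDs): single-sine degree-day
    accumulation with lower and upper thresholds and a horizontal cutoff,
    data-driven calibration of the base development threshold from
    cross-year consistency of at-adulthood GDDs, screening of accidental
    adult records, phenological-advancement statistics (paired tests,
    advancement-versus-timing models, abundance-change correlations,
    GDD-elevation regressions), and a synthetic daily-weather and survey
    generator for end-to-end validation of the pipeline, including
    warming-timing scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
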