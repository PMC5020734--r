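Package: coralmpm
Title: Inverse-Estimated Matrix Population Models for Coral Size-Frequency Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates stage-transition (Leslie) matrices from irregular
    coral size-frequency survey series by constrained least squares (Wood's
    method) under a life-cycle constraint graph, verifies the estimate by
    hindcast with recruit augmentation, and projects 100-year population and
    percent-cover trajectories under Ricker density dependence, truncated
    Gaussian imported recruitment, and random pulse disturbances. Includes a
    synthetic-data generator emulating variable transect effort, missing
    survey years and size-class-1 under-detection, plus effort
    standardization, proportional scaling and regression imputation of
    missing years.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    pracma,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
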