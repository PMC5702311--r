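Package: loadperf
Title: Global Training Load Metrics and Dose-Response Modelling of Match Performance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for athlete load monitoring in team sport: computes a
    weighted "global load" from GPS-derived external load and perceived
    wellness, derives smoothed (exponentially weighted), differential,
    monotony, strain and acute:chronic training measures, estimates
    quadratic dose-response effects of each measure on match performance
    with player-level mixed models, and interprets effects with
    standardization and magnitude-based inference. Includes a synthetic
    season generator with known ground truth for validating the whole
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    lme4,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
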