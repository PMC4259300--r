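Package: biatscore
Title: Scoring and Psychometric Evaluation of the Brief Implicit Association Test
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving association scores from trial-level Brief
    Implicit Association Test (BIAT) response latencies. Implements the
    recommended D transformation together with the full data-treatment
    pipeline (hard latency cutoff, warm-up trial removal, error-trial policy,
    latency tail recoding or deletion, and respondent exclusion rules), the
    competitor difference-score transformations (raw latency, log, and
    reciprocal differences), and a psychometric evaluation battery:
    split-half internal consistency, Fisher z-averaged criterion
    correlations, latency operating characteristics over response-speed
    deciles, and polynomial stability regressions. A seeded trial-level
    simulator with per-subject speed and mean-variance coupling supports
    end-to-end testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
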