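Package: nutrilight
Title: Traffic-Light Scoring of Daily Food-Group Intakes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the NutriLight dietary scoring system: each of 15 food
    groups is assigned to a green (encouraged), yellow (moderation) or red
    (limited) traffic-light category and a subject-day's intake of each group is
    scored 0, 1 or 2 points against an EAT-Lancet-derived recommended amount,
    giving a total score of 0-30. Provides the piecewise scoring engine with
    category subscores and a balance index, energy adjustment of the reference
    amounts, CSV readers and writers for dietary records, longitudinal
    aggregation (mean score, adherence trend, cumulative classification), a
    seeded synthetic-diet simulator with controllable adherence, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
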