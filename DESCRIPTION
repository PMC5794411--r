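Package: etamu
Title: Weighted Deficit Indices for Separating Visuoperceptive from
    Visuomotor-Coordination Impairment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Scores psychometric test batteries with the Eta-Mu model:
    each test in a battery is assigned visuoperceptive (VP) and
    visuomotor-coordination (VMC) recruitment weights summing to 100, and a
    child's z-score profile is condensed into weighted impairment indices
    eta (VP) and mu (VMC), expected baselines under balanced impairment,
    and a deficit classification. Handles incomplete batteries by
    reweighting over the administered subset, summarises cohorts with
    Tukey-hinge interquartile ranges, compares pre/post-treatment sessions
    with paired signed-rank tests, and simulates synthetic subjects with
    controlled VP/VMC severities for validation and parameter recovery.
    Includes tidy data-frame verbs, ggplot2 plotting methods, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
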