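Package: salmospec
Title: Testis Transcriptome Specific Activity and Maturation Analysis for
    Atlantic Salmon
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Links testis growth (gonadosomatic index, GSI) in Atlantic salmon
    to endocrine state and transcriptome specific activity. Provides GSI-based
    maturity grouping and biometric indices, per-gene differential specific
    activity classification (HSA/LSA) between pubertal and immature testes by
    log2 expression ratio and t-test, gonad-specific gene calling from a
    multi-tissue expression compendium, functional-group mean-shift testing,
    serum hormone statistics, and a seeded synthetic-data generator built on a
    two-compartment (germinative/interstitial) testis growth model with planted
    ground truth for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
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
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
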