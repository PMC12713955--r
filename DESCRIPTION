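Package: circsleep
Title: Circadian Sleep Health from Actigraphy, Salivary Melatonin, and Self-Report
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for multimodal adolescent circadian
    sleep-health analysis: Sadeh sleep/wake scoring of wrist actigraphy counts,
    nightly sleep onset/offset/midsleep summaries, dim-light melatonin onset
    (DLMO) estimation from salivary concentration series by 4 pg/mL threshold
    crossing, phase angle of entrainment and social jetlag, dichotomous
    circadian groupings (early/late phase, aligned/misaligned, minimal/present
    social jetlag, eveningness/morningness chronotype), and covariate-adjusted
    general linear models of mental-health outcomes reported with partial eta
    squared. Includes a fully seeded synthetic cohort generator emitting raw
    epoch-level activity traces, sleep diaries, melatonin series, and survey
    tables with known ground truth, so the whole chain is testable end to end
    without external data.
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
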