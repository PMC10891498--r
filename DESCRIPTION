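Package: dietvalid
Title: Relative-Validity Analysis of Dietary Assessment Methods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computational pipeline for relative-validity studies of dietary
    assessment instruments. Converts raw food-record entries to daily
    food-group and nutrient intakes via a food-composition table (portion
    weights, density, edible fraction, preparation yield, fat absorption),
    screens participant-days for implausible energy reporting against
    Henry-equation basal metabolic rate (Goldberg-type energy-intake/BMR
    cutoffs), selects matched comparators from an external pool with
    stepwise relaxation, and runs the paired-method comparison battery
    (Wilcoxon signed rank with normal approximation, McNemar, Spearman rank
    correlation, Bland-Altman limits of agreement, and >10 percent relevance
    flagging). A synthetic-data generator produces complete paired studies
    with known ground-truth bias and rank correlation for validation of
    every pipeline stage.
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
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
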