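Package: nanosig
Title: Single-Molecule Nanogap Current Signal Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying monoamine neurotransmitters (dopamine,
    norepinephrine, serotonin) from single-molecule tunnelling-current
    measurements in mechanically controllable break-junction nanogaps.
    Provides a seeded trace simulator, pulse detection with robust baseline
    estimation, ten-region feature extraction with current-fluctuation
    statistics, two-round positive-unlabeled (PU) noise removal, a
    cross-validated gradient-boosted-tree classifier, and plurality-vote
    aggregation with exact trinomial vote-accuracy calculations and
    mixture-composition estimates with simultaneous multinomial confidence
    intervals.
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
    utils,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
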