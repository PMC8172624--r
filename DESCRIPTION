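Package: penfluency
Title: Pen-Movement Fluency Analysis for Beginning Handwriting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing pen-tip movement fluency in digitiser
    handwriting data from beginning writers. Reads timestamped pen traces
    and sub-letter feature mark-up, computes tangential velocity profiles
    with zero-phase Butterworth low-pass filtering, counts velocity peaks
    to obtain per-feature disfluency scores and the signal-to-noise
    velocity peaks difference (SNvpd), applies a rule-based accuracy coder
    to letter features, scores pen-control and letter-knowledge tasks, and
    orchestrates nested linear mixed-effects model comparison sequences.
    Includes a synthetic handwriting generator (minimum-jerk sub-movement
    traces with tremor, defect injection, and full cohorts with known
    ground truth) for validation and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    MASS,
    lme4,
    lmerTest
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
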