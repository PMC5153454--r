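Package: nutriclaim
Title: Nutrient Profiling and Health-Claim Analysis of Pre-Packaged Food Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for cross-sectional surveys of
    pre-packaged foods and the health-related claims on their labels.
    Reads per-100 g nutrient declarations with provenance tracking,
    resolves structured claim annotations into health and nutrition
    claims under a configurable taxonomy with exclusion screening,
    scores foods with the Food Standards Australia New Zealand Nutrient
    Profiling Scoring Criterion (FSANZ NPSC), supplements missing
    declarations from a matched food-composition databank with
    correlation-based validation, and compares the nutritional quality
    of claim-bearing and claim-free foods via rank tests,
    category-adjusted regression, and proportion estimates with
    confidence intervals. Includes a stratified five-country survey
    simulator with ground-truth bookkeeping for parameter-recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
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
    e1071,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
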