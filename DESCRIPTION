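Package: regionvar
Title: Morbidity-Adjusted Analysis of Regional Variation in Health-Care
    Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing regional health-care efficiency and
    quality outcomes after adjusting for population morbidity via a
    categorical population classification ("PopGroups"). Implements
    indirect standardization (crude, age-sex, and PopGroup-standardized
    observed-to-expected ratios), the small-group aggregation rule onto
    macro groups, multilevel random-intercept and random-slope models for
    log-linear and logistic outcomes with variance decomposition
    (intraclass correlation), per-region odds ratios and
    regression-adjusted O/E ratios, ranked distribution diagrams, and a
    synthetic claims-panel generator with known ground truth for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    ggplot2,
    jsonlite,
    yaml,
    pracma,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
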