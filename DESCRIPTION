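Package: msrs
Title: Psychometric Validation Toolkit for the Macaque Social Responsiveness Scale
Version: 0.1.0
Authors@R:
    person("mSRS", "Maintainers", email = "msrs@example.org", role = c("aut", "cre"))
Description: Scoring, score-distribution analysis, inter-rater and item-level
    reliability, and bootstrapped exploratory factor analysis for multi-rater
    ordinal surveys of the macaque Social Responsiveness Scale (mSRS) family.
    Includes reverse-keyed scoring with strict or prorated handling of skipped
    items, Lilliefors normality testing with Monte-Carlo p-values, two-way
    mixed average-measures intraclass correlations computed pairwise over
    raters sharing subjects, per-item Cronbach's alpha with zero-variance and
    negative-alpha exclusion rules, eigenvalue bootstrap factor retention,
    maximum-likelihood factor extraction with varimax rotation, bootstrap
    median loadings with percentile confidence intervals and Tucker-congruence
    factor alignment, and a latent-factor generator of synthetic multi-rater
    ordinal survey data with known ground truth so the full pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    readxl,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
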