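Package: motionmargins
Title: Internal Margins for Intra-Fractional Prostate Motion from
    Moment and REML Variance Components
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analyses time-sampled intra-fractional prostate motion traces
    (superior-inferior, anterior-posterior, left-right; millimetres) from
    image-guided radiotherapy and converts them into internal treatment
    margins.  Provides a hierarchical synthetic trace generator (patient,
    fraction and intra-fraction variance components, baseline drift,
    transient rectal-gas excursions), a documented long-format text
    interchange for cohorts, descriptive displacement summaries with
    rank-sum comparisons between delivery techniques, variance-component
    estimation by both classic moment definitions and a from-scratch
    restricted maximum likelihood (REML) fit of the nested
    fraction-within-patient random-effects model with profile-likelihood
    confidence intervals, conversion to effective systematic and random
    errors for a finite number of fractions, and the 2.5*Sigma + 0.7*sigma
    margin recipe.
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
    yaml
Suggests:
    lme4,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
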