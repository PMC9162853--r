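Package: ineqdid
Title: Income-Related Inequality in Health and Healthcare with
    Concentration Indices and Time-Varying Difference-in-Differences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Measures and decomposes income-related inequality in health
    outcomes, healthcare utilization and out-of-pocket medical spending.
    Provides concentration curves and concentration indices with respect
    to the fractional income rank, regression-based (Wagstaff)
    decomposition of a concentration index into factor contributions via
    elasticities, population-share between/within group decompositions,
    and Oaxaca-type decomposition of the change in a factor's
    contribution over time.  The policy effect entering the decomposition
    is estimated by a two-way fixed-effects linear probability model with
    a staggered (time-varying) treatment indicator, with
    heteroskedasticity-robust or cluster-robust standard errors,
    propensity-score-matched re-estimation on the common support, and an
    individual- or city-level placebo permutation test.  A seeded
    synthetic panel generator emulates a multi-wave household survey with
    individuals nested in cities and a staggered, wealth-correlated
    city-level insurance rollout, so the full pipeline is testable
    without access-restricted microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    sandwich,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
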