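# ineqdid

Income-related inequality in health and healthcare, measured by
concentration indices and decomposed around a staggered policy rollout.

## What problem this solves

Health economists and epidemiologists studying a policy that is adopted
city by city — here, the integration of residents' basic medical
insurance across urban and rural schemes — typically need to answer two
linked questions from individual-level panel data:

1. **Did the policy work?**  Estimated with a time-varying
   difference-in-differences (two-way fixed effects) regression
   `y_ict = α + β·T_ct + X'θ + μ_c + ϑ_t + ε_ict`, where the treatment
   indicator `T_ct` switches on at city-specific adoption times.
2. **Who did it favour?**  Measured by the concentration index
   `CI(y|I) = 2 cov(y, r) / ȳ` with `r` the fractional income rank
   (positive = concentrated among the rich), and attributed to factors
   by the Wagstaff decomposition
   `CI(y|I) = Σ_k (ρ_k x̄_k / ȳ) · CI(x_k|I) + GC(ε)/ȳ`,
   whose per-factor terms are elasticity × factor inequality.

On top of these, the package provides between/within group
decompositions (urban/rural, east/non-east), an Oaxaca-type split of a
contribution's change over time into a CI-change part and an
elasticity-change part, PSM-DID re-estimation on the common support, a
placebo permutation test, and a seeded synthetic panel generator that
emulates the restricted survey data these methods are usually applied
to (three waves, individuals nested in cities, wealth-correlated
staggered adoption with "pro-rich" coverage inequality around 0.10).
Because the generator's truth is known, every estimator and identity in
the package is tested against it.

## Worked example

```r
library(ineqdid)

panel <- generate_panel(synthetic_config(n_individuals = 5000,
                                         n_cities = 30, seed = 42))
factors <- c("urrbmi", "age", "age2", "male", "married", "hhnum",
             "lnpcincome", "rural", "priedu", "secedu", "highedu",
             "superhigh", "pension", "sanitary")

concentration_index(panel$healthy, panel$lnpcincome,
                    outcome_name = "healthy")
#> Concentration index of healthy: 0.0786
#>   mean outcome 0.5559 on n = 15000 (covariance formula)
```

Self-rated health is concentrated among higher-income respondents
(pro-rich inequality).  The policy effect and its role in that
inequality:

```r
fit <- fit_did(panel, "healthy", factors)
dec <- wagstaff_decompose(fit, panel)
dec
#> Wagstaff decomposition of CI(healthy) = 0.0786 (mean 0.5559, n = 15,000)
#>      factor coefficient     mean elasticity factor_ci contribution contribution_rate
#>      urrbmi      0.0213   0.1499     0.0057    0.0913       0.0005            0.6677
#>  lnpcincome      0.0399   8.6900     0.6240    0.1069       0.0667           84.8700
#>      ...
#> Residual: 0.0023 (2.96%)
```

Reading the coverage (`urrbmi`) row: insurance coverage raises the
probability of good health by 2.1 points (the generator's true effect
is 2.43, well inside the confidence interval at this sample size), and
coverage itself is pro-rich (factor CI 0.0913), so the policy
contributes positively — about 0.7% — to health inequality.  Income
dominates the decomposition (85% of the total), mainly through its
large elasticity.  The rows plus the residual sum to the total CI
exactly; the suite asserts this identity at 1e-10.

A placebo check that the estimated effect is not an artefact of the
specification:

```r
placebo_test(panel, "healthy", factors, R = 200, seed = 42)
#> Placebo test for 'healthy' (individual-level reassignment, R = 200)
#>   observed estimate 0.0213; placebo mean 0.0000 (sd 0.0118)
#>   two-sided tail proportion: 0.070
```

Under random reassignment the estimates center on zero; the observed
coefficient sits in the tail (at this deliberately small n the tail
proportion is 7%; it vanishes at the default study size).

The whole analysis — all five outcomes, group and period
decompositions, PSM-DID and placebo — runs as one configured, seeded,
reproducible bundle:

```r
run_pipeline(pipeline_config(synthetic_config(seed = 1),
                             output_dir = "report"))
```

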