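---
title: "Measuring and decomposing income-related inequality with a staggered policy rollout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and decomposing income-related inequality with a staggered policy rollout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ineqdid)
```

## The problem

When a health-insurance scheme is rolled out city by city, two questions
arise together: does coverage improve health and healthcare use, and does
it narrow or widen the gap between rich and poor?  `ineqdid` implements
the standard toolkit for answering both at once: concentration indices to
measure income-related inequality, a two-way fixed-effects linear model
with a staggered (time-varying) treatment indicator to estimate the
policy effect, and a family of decompositions that connect the two.

The motivating setting is a residents' basic medical insurance
integration in China, observed over three biennial survey waves while
adoption was still voluntary at the city level and correlated with city
wealth.  The original microdata are access-restricted, so the package
ships a synthetic-data generator that reproduces the relevant structure
with known parameters; every statistical claim the package makes is
tested against that known truth.

## Concentration curves and the concentration index

Individuals are ranked by income.  With midpoint fractional ranks
$r_i = (R_i - 0.5)/n$ (ties receive the average of their positional
ranks, so the ranks always average exactly one half), the concentration
index of an outcome $y$ is computed by the convenient covariance formula

$$CI(y|I) = \frac{2\,\mathrm{cov}(y, r)}{\bar y},$$

with the population (divisor-$n$) covariance.  Equivalently, $CI$ is one
minus twice the area under the concentration curve (cumulative outcome
share against cumulative population share by income rank).  The package
implements both routes: `concentration_index()` is canonical and
`concentration_curve()` + `ci_from_curve()` is the cross-check.  Two
numerical conventions make the routes agree to machine precision rather
than approximately, and both are pinned in tests:

* the covariance uses divisor $n$, matching the trapezoid geometry of
  the piecewise-linear curve;
* tied incomes are pooled into a single curve segment and share one
  averaged rank, which makes the curve well defined under ties and
  equals the average over all tie orderings of the per-observation
  curve.

A positive index means the outcome is concentrated among richer
individuals ("pro-rich").  For burden-type outcomes such as
out-of-pocket spending, a positive index means the burden falls on the
rich, i.e. inequality favouring the poor.  No rescaling for bounded
(binary) outcomes is applied: the plain index is used throughout, and
normalised variants (Erreygers, Wagstaff) are deliberately out of scope.
Outcomes with negative values (possible for logged expenses below one
unit) are permitted with a warning; the $|CI| \le 1$ bound is only
guaranteed for non-negative outcomes.  All computations are unweighted
by default; `fractional_rank()` and `concentration_index()` accept
optional sampling weights.

## The policy regression

The effect of coverage enters through a linear probability model with
city and year fixed effects,

$$y_{ict} = \alpha + \beta\,T_{ct} + X_{ict}'\theta + \mu_c +
\vartheta_t + \varepsilon_{ict},$$

where $T_{ct}$ switches on at the city's adoption time and stays on.
Binary outcomes are estimated by OLS rather than probit/logit for
internal consistency: the decomposition below needs linear coefficients,
and the reported constant and $R^2$ are then conventional.  Standard
errors are heteroskedasticity-robust (HC1) by default with a
cluster-robust option (`se_type = "cluster"`), computed via the
`sandwich` estimators.  `fit_did()` refuses two degenerate designs
explicitly rather than silently mis-reporting: a treatment with no
variation, and a treatment perfectly absorbed by the fixed effects (the
latter is detected by projecting the treatment on the dummy space, since
`lm()` would otherwise drop a dummy and leave a confounded coefficient).
Log-expense outcomes are estimated conditional on use — rows where the
expense is unobserved (no utilization) drop out of the estimation
sample — mirroring the two-part structure of medical spending data.

Heterogeneity along the income distribution is exposed by
`fit_by_income_quartile()`, which cuts quartiles on pooled sample
quantiles; observations tied exactly at a boundary go to the lower
quartile.

## Wagstaff decomposition

With elasticities $\eta_k = \rho_k \bar x_k / \bar y$ evaluated at
sample means, the outcome's index splits additively:

$$CI(y|I) = \sum_k \eta_k\, CI(x_k|I) + \frac{GC(\varepsilon)}{\bar y},$$

where $GC(\varepsilon) = 2\,\mathrm{cov}(\varepsilon, r)$ is the
generalized concentration index of the regression residual.  Because the
regression is linear and the index and regression share the sample, this
identity is exact, and the test suite asserts it at `1e-10` on every
fixture.  The residual term is scaled by the outcome mean $\bar y$; a
variant sometimes printed with mean income in the denominator does not
close the identity and is not used.  Two presentation choices follow the
conventional tabulation:

* city and year dummies are not listed as factors; their contribution is
  absorbed into the residual row (set `include_fe = TRUE` to list them,
  in which case the residual reduces to the pure error-term component —
  the package verifies the two variants describe the same total);
* contribution rates are reported as contribution divided by the total
  index, in percent, even when that produces negative rates.

A factor whose sample mean is zero has no well-defined elasticity or own
index, but its contribution $\rho_k \cdot 2\,\mathrm{cov}(x_k, r)/\bar y$
is still computed directly, so the identity never breaks.

## Between/within group decomposition

For a partition such as urban/rural or east/non-east,

$$CI(y|I) = \sum_g \frac{N_g}{N} CI_g(y|I) + CI_{between},$$

where each within-group index is computed on the subsample with its own
internal income ranking, and the between term is defined as the residual
of the identity.  The residual definition is a deliberate choice: the
intergroup term is never defined constructively in this literature's
population-share form, and defining it as the residual both makes the
identity testable and reproduces published group-decomposition
arithmetic.  When a regression specification is supplied,
`decompose_by_group()` also refits the model inside each group and
reports the policy factor's within-group index and contribution rate;
the between row's contribution is the bookkeeping residual
(overall contribution minus share-weighted group contributions).  Those
per-group rates are genuinely per-group objects and need not aggregate
to the overall rate in any simple way.

## Change decomposition over time

`per_period_tables()` refits the factor regression wave by wave and
decomposes each wave separately.  Within a single wave a city-level
treatment is constant within city, so city fixed effects would absorb
it; the per-wave fits therefore default to the plain cross-sectional
factor regression (`fe = NULL`).  The change in a factor's contribution
between waves then splits exactly:

$$\Delta(\eta_k CI_k) = \eta_{k,t-1}\,\Delta CI(x_k|I) +
CI_t(x_k|I)\,\Delta\eta_k .$$

The default weighting (lagged elasticity on the CI change, current CI on
the elasticity change) reproduces published change-decomposition
arithmetic; the symmetric alternative — current elasticity with the CI
change, lagged CI with the elasticity change — sums to the same total
and is available via `weighting = "current_elasticity"`.

## Robustness tools

**PSM-DID.**  `psm_did()` estimates a logit propensity score of
treatment on the covariate set, trims to the common support (the overlap
of treated and control score ranges), matches each treated unit to its
nearest control by score (1-NN with replacement, optional caliper), and
refits the DID model.  The estimation sample is the support-trimmed
sample: support trimming is what produces the characteristically small
drop in $n$, while the recorded matches serve balance diagnostics
(`match_balance()`).  The propensity specification and matching scheme
are stated assumptions, not facts about any particular study; matching
is deliberately the simplest scheme (no kernel/radius/Mahalanobis
variants, no bootstrap-corrected standard errors).

**Placebo test.**  `placebo_test()` re-estimates the policy coefficient
under random reassignment of treatment, by default permuting the
indicator across individuals within each wave so the per-wave treated
fraction is preserved exactly; `level = "city"` instead permutes whole
city adoption histories across cities, respecting the level at which
treatment is actually assigned.  Each replicate uses the
Frisch–Waugh–Lovell projection — covariates and dummies are partialled
out of the outcome once and out of each reassigned treatment vector —
so the observed estimate equals the full OLS coefficient exactly and a
replicate costs one projection.  The kernel-density export
(`placebo_density()`) uses a Gaussian kernel with Silverman's
rule-of-thumb bandwidth; this is cosmetic.

## The synthetic panel generator

`generate_panel()` draws a balanced persons-by-waves panel intended to
emulate a three-wave labour-force survey under a staggered insurance
integration.  The defaults are the package's fixed study conditions:

* 20,000 persons in 60 cities over waves 2012/2014/2016 (tests use
  smaller panels, typically 400–2,500 persons in 6–15 cities);
* log income = overall location 8.642 + city effect (s.d. 0.5) +
  persistent person effect (s.d. 1.0, shifted by education and rural
  status) + transient wave noise (s.d. 1.105), giving an overall s.d.
  near 1.59;
* city adoption: a city at wealth percentile $p$ has adopted by wave
  $j$ with probability $q_j (a+1) p^a$, where $q_j$ are the coverage
  targets (0.0985, 0.1479, 0.2717) and $a$ the steepness.  Adoption is
  drawn once per city from a single uniform, so it is absorbing by
  construction.  The steepness default $a = 1$ was calibrated once so
  the pooled coverage concentration index sits near 0.10 — the stated
  "pro-rich" coverage inequality of the emulated setting — while the
  expected per-wave coverage equals the targets exactly;
* binary outcomes are Bernoulli with *linear* probabilities: a latent
  linear index plus uniform noise and a threshold, the threshold
  (intercept) calibrated so realised means match the targets (healthy
  0.557, outpatient 0.087, hospital 0.081).  A Gaussian latent threshold
  was rejected on purpose: it would make the linear probability model
  misspecified and the configured coefficients unrecoverable, defeating
  the point of a generator with known truth.  Linear probabilities can
  clip at 0/1 for extreme covariate profiles; the realised clip share is
  recorded in the panel's `truth` attribute (about 1–2% for the health
  outcome under defaults, a negligible attenuation relative to sampling
  noise);
* log expenses are Gaussian conditional on the matching utilization
  flag, with the policy effect on expenses optionally varying across
  pooled income quartiles (`expense_quartile_gradient`, default 0.25 per
  quartile step) so that the configured stronger burden reduction for
  poorer users is a testable ground truth.

What the generator does **not** emulate: survey sampling weights and
design, geographic structure beyond city labels, income deflation (all
monetary values are generated as already-deflated logs), attrition and
rotation (the panel is balanced), and within-city outcome correlation
beyond what shared city income effects induce.  Passing tests therefore
demonstrate correctness of the estimators and identities under a clean
data-generating process, not robustness to the messiness of real survey
data.

With few cities and modest coverage targets, a small fraction of seeds
draws a panel in which no city ever adopts, or in which the adoption
pattern is absorbed by the fixed effects.  These draws carry no
identifying variation; `fit_did()` reports them as inestimable, and
seed-loop tests move deterministically to the next seed.

## Numerical choices and degenerate inputs

* Population (divisor-$n$) covariance everywhere; this is what makes the
  covariance/curve and decomposition identities exact rather than
  approximate.
* An outcome with zero mean has an undefined index and raises an error;
  groups or waves where this happens are flagged, not silently skipped.
* Quartile boundary ties go to the lower quartile.
* Collinear covariates are dropped with a warning; a collinear or
  constant *treatment* is an error, because a silently re-identified
  treatment coefficient would be meaningless.
* All randomness is seed-controlled: the generator seeds itself from its
  config, the placebo test takes an explicit seed, and
  `run_pipeline()` reruns byte-identically under a fixed configuration.

## The pipeline

`run_pipeline(pipeline_config(...))` ties the stages together for one
dataset (a data frame, a synthetic config, or a CSV path) and writes a
report bundle: DID estimates, pooled decompositions, group
decompositions, per-wave tables, contribution-change splits, PSM-DID and
placebo outputs, a full-precision `results.json`, an `identities.json`
recording every additivity check, and a deterministic log.  Tables are
formatted at 4 decimals (rates at 2) with full precision preserved in
the JSON.  The package is R-native; its interface is these functions
rather than a shell tool, and `scripts/acceptance.R` shows a complete
scripted run.

## Known limitations

* Plain two-way fixed effects with staggered adoption is used as-is;
  heterogeneity-robust staggered-DID estimators are out of scope.
* The decomposition attributes inequality through a linear model;
  nonlinear (probit marginal-effects) decompositions are not provided.
* Per-group contribution rates for between-group rows are bookkeeping
  residuals and should be read as such.
* The concentration index for binary outcomes depends on the outcome
  mean; comparisons across populations with very different means should
  be made with care (no normalisation is applied).
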