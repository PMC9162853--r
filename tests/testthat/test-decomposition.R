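test_that("elasticity is rho * mean_x / mean_y with guarded denominator", {
  expect_equal(elasticity(0, 3.2, 0.5), 0)
  expect_equal(elasticity(c(1, 2), c(2, 3), 4), c(0.5, 1.5))
  expect_error(elasticity(1, 1, 0), "nonzero")
})

test_that("an exactly linear outcome decomposes with zero residual", {
  set.seed(13)
  n <- 40
  d <- data.frame(city_id = 1, year = 1,
                  treat = rbinom(n, 1, 0.5), x = rnorm(n, 2),
                  income = rlnorm(n))
  d$y <- 0.4 + 0.7 * d$treat + 0.3 * d$x  # no noise
  f <- suppressWarnings(fit_did(d, "y", c("treat", "x"), fe = NULL))
  dec <- wagstaff_decompose(f, d, income = "income")
  expect_equal(dec$residual_contribution, 0, tolerance = 1e-12)
  expect_equal(sum(dec$rows$contribution), dec$total_ci, tolerance = 1e-12)
  expect_equal(sum(dec$rows$contribution_rate), 100, tolerance = 1e-8)
})

test_that("the residual term is the generalized CI of the regression error", {
  # non-circular form of the additive identity: with no absorbed dummies
  # total CI - sum(contributions) must equal 2 cov(e, r) / ybar
  for (s in 1:6) {
    set.seed(s)
    n <- 120
    d <- data.frame(city_id = rep(1:4, 30), year = rep(1:2, 60),
                    treat = rbinom(n, 1, 0.4), x1 = rnorm(n, 1),
                    x2 = runif(n), income = rlnorm(n))
    d$y <- 0.2 + 0.5 * d$treat - 0.3 * d$x1 + d$x2 + rnorm(n, 0, 0.3)
    f <- fit_did(d, "y", c("treat", "x1", "x2"), fe = NULL)
    dec <- wagstaff_decompose(f, d, income = "income")
    expect_equal(dec$residual_contribution, dec$error_gci,
                 tolerance = 1e-10)
  }
})

test_that("fixed effects default into the residual and can be listed", {
  p <- small_panel_treated(seed = 17, n = 500, cities = 6)
  f <- suppressWarnings(
    fit_did(p, "healthy", c("urrbmi", "age", "lnpcincome")))
  dec <- wagstaff_decompose(f, p)
  expect_equal(nrow(dec$rows), 3)
  expect_equal(sum(dec$rows$contribution) + dec$residual_contribution,
               dec$total_ci, tolerance = 1e-12)
  # listing the absorbed dummies shrinks the residual to the error term
  dec_fe <- wagstaff_decompose(f, p, include_fe = TRUE)
  expect_gt(nrow(dec_fe$rows), 3)
  expect_equal(dec_fe$residual_contribution, dec_fe$error_gci,
               tolerance = 1e-10)
  # both variants describe the same total
  expect_equal(dec_fe$total_ci, dec$total_ci)
})

test_that("decomposition matches a from-first-principles recomputation", {
  set.seed(23)
  n <- 25
  d <- data.frame(city_id = 1, year = 1, treat = rbinom(n, 1, 0.5),
                  x = rnorm(n, 3), income = rlnorm(n))
  d$y <- 1 + 0.6 * d$treat + 0.2 * d$x + rnorm(n, 0, 0.4)
  f <- fit_did(d, "y", c("treat", "x"), fe = NULL)
  dec <- wagstaff_decompose(f, d, income = "income")

  # oracle: explicit sums with positional ranks
  R <- rank(d$income, ties.method = "average")
  r <- (R - 0.5) / n
  ybar <- mean(d$y)
  total_oracle <- 2 * (sum(d$y * r) / n - mean(d$y) * mean(r)) / ybar
  expect_equal(dec$total_ci, total_oracle, tolerance = 1e-12)
  for (k in c("treat", "x")) {
    rho <- f$coefficients[[k]]
    x <- d[[k]]
    cov_xr <- sum(x * r) / n - mean(x) * mean(r)
    contr_oracle <- rho * 2 * cov_xr / ybar
    i <- match(k, dec$rows$factor)
    expect_equal(dec$rows$contribution[i], contr_oracle, tolerance = 1e-12)
    expect_equal(dec$rows$elasticity[i] * dec$rows$factor_ci[i],
                 contr_oracle, tolerance = 1e-12)
  }
})

test_that("a pro-rich factor with a positive coefficient contributes positively", {
  set.seed(31)
  n <- 400
  income <- rlnorm(n)
  treat <- as.integer(rank(income) / n + runif(n, -0.3, 0.3) > 0.5)
  d <- data.frame(city_id = 1, year = 1, treat = treat, income = income)
  d$y <- 0.3 + 0.5 * treat + rnorm(n, 0, 0.1)
  f <- fit_did(d, "y", "treat", fe = NULL)
  dec <- wagstaff_decompose(f, d, income = "income")
  i <- match("treat", dec$rows$factor)
  expect_gt(dec$rows$factor_ci[i], 0)
  expect_gt(dec$rows$coefficient[i], 0)
  expect_gt(dec$rows$contribution[i], 0)
})

test_that("a fit cannot be decomposed against mismatched data", {
  p <- small_panel_treated(seed = 19, n = 400, cities = 6)
  f <- suppressWarnings(fit_did(p, "healthy", c("urrbmi", "age")))
  other <- p
  other$healthy <- rev(other$healthy)
  expect_error(wagstaff_decompose(f, other), "mismatch")
  expect_error(wagstaff_decompose(f, p[1:10, ]), "rows")
})
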