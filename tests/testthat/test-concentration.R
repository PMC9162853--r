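test_that("midpoint fractional ranks handle ties and average to one half", {
  expect_equal(fractional_rank(c(10, 20, 30)), c(1, 3, 5) / 6)
  expect_equal(fractional_rank(rep(7, 4)), rep(0.5, 4))
  # tied pair averages its positional ranks 1/6 and 3/6
  expect_equal(fractional_rank(c(5, 5, 9)), c(1/3, 1/3, 5/6))

  set.seed(41)
  for (n in c(3, 10, 57, 200)) {
    inc <- sample(round(rlnorm(n), 1), n, replace = TRUE)  # forces ties
    r <- fractional_rank(inc)
    expect_equal(mean(r), 0.5, tolerance = 1e-14)
    expect_true(all(r > 0 & r < 1))
    # weighted ranks with equal weights match the unweighted ones
    expect_equal(fractional_rank(inc, weights = rep(2, n)), r,
                 tolerance = 1e-12)
    w <- runif(n, 0.5, 3)
    rw <- fractional_rank(inc, w)
    expect_equal(sum(w / sum(w) * rw), 0.5, tolerance = 1e-12)
  }
  expect_error(fractional_rank(numeric(0)), "nonempty")
  expect_error(fractional_rank(c(1, NA)), "missing")
})

test_that("covariance-formula index matches hand computation and its invariances", {
  inc <- 1:5
  r <- fractional_rank(inc)
  # outcome equal to the rank itself: 2 var_pop(r) / 0.5 = 0.32
  expect_equal(concentration_index(r, inc)$value, 0.32)
  # constant outcome carries no inequality
  expect_equal(concentration_index(rep(3, 8), 1:8)$value, 0)

  set.seed(7)
  y <- rbinom(60, 1, 0.4) + 0.01
  inc <- rlnorm(60)
  ci <- concentration_index(y, inc)$value
  # scale invariance and rank-reversal antisymmetry
  expect_equal(concentration_index(2 * y, inc)$value, ci, tolerance = 1e-12)
  expect_equal(concentration_index(y, -inc)$value, -ci, tolerance = 1e-12)
  # agrees with an independent positional-rank oracle
  expect_equal(ci, ci_positional(y, inc), tolerance = 1e-12)
  # bounded for non-negative outcomes
  for (s in 1:20) {
    set.seed(s)
    yy <- rexp(30)
    expect_lt(abs(concentration_index(yy, rnorm(30))$value), 1)
  }

  expect_error(concentration_index(c(0, 0), c(1, 2)), "mean is zero")
  expect_error(concentration_index(1:3, 1:4), "same length")
  expect_warning(concentration_index(c(-1, 2, 3), 1:3), "negative")
})

test_that("concentration curve has correct endpoints and degenerate shapes", {
  # equal outcome for all: curve lies on the Fair Line
  cv <- concentration_curve(rep(1, 5), c(3, 1, 4, 2, 5))
  expect_equal(cv$points$C, cv$points$q, tolerance = 1e-14)
  expect_equal(ci_from_curve(cv), 0, tolerance = 1e-14)

  # all outcome held by the richest of four
  cv <- concentration_curve(c(0, 0, 0, 1), c(1, 2, 3, 4))
  expect_equal(cv$points$q, c(0, 0.25, 0.5, 0.75, 1))
  expect_equal(cv$points$C, c(0, 0, 0, 0, 1))

  # hand-computed toy: covariance and curve routes both give 1/3
  y <- c(0, 1, 1); inc <- c(1, 2, 3)
  expect_equal(ci_from_curve(concentration_curve(y, inc)), 1 / 3,
               tolerance = 1e-14)
  expect_equal(concentration_index(y, inc)$value, 1 / 3, tolerance = 1e-14)

  # first/last point pinned at (0,0) and (1,1); ties pooled
  cv <- concentration_curve(c(1, 2, 3, 4), c(5, 5, 1, 1))
  expect_equal(cv$points$q, c(0, 0.5, 1))
  expect_equal(cv$points$C, c(0, 7 / 10, 1))

  expect_error(concentration_curve(c(0, 0), 1:2), "positive")
})
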