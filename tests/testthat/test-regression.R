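test_that("noise-free two-city panel recovers the constructed effect exactly", {
  d <- expand.grid(city_id = c("A", "B"), year = c(1, 2), rep = 1:2)
  d$treat <- as.integer(d$city_id == "B" & d$year == 2)
  d$y <- 1 + 0.5 * (d$city_id == "B") + 0.25 * (d$year == 2) + 0.3 * d$treat
  f <- suppressWarnings(fit_did(d, "y", "treat"))  # exact fit
  expect_equal(f$coefficients[["treat"]], 0.3, tolerance = 1e-10)
  expect_equal(f$r_squared, 1, tolerance = 1e-10)
  expect_equal(sum(f$residuals), 0, tolerance = 1e-10)
})

test_that("degenerate designs raise explicit errors", {
  p <- small_panel(seed = 2, n = 300, cities = 6)
  p$urrbmi <- 0L
  expect_error(fit_did(p, "healthy", c("urrbmi", "age")), "no variation")
  p2 <- small_panel(seed = 2, n = 300, cities = 6)
  p2$healthy <- 1L
  expect_error(fit_did(p2, "healthy", c("urrbmi", "age")), "constant")
  # a constant covariate is dropped with a warning, not an error
  p3 <- small_panel(seed = 2, n = 300, cities = 6)
  p3$male <- 1L
  expect_warning(f <- fit_did(p3, "healthy", c("urrbmi", "age", "male")),
                 "dropped")
  expect_false("male" %in% f$factors)
  # treatment collinear with the fixed effects is inestimable
  one_wave <- p3[p3$year == 2014, ]
  expect_error(suppressWarnings(
    fit_did(one_wave, "healthy", c("urrbmi", "age"), fe = "city_id")),
    "inestimable")
})

test_that("dummy-variable OLS equals the within transformation", {
  for (s in 1:4) {
    p <- small_panel_treated(seed = s, n = 400, cities = 8)
    f <- suppressWarnings(
      fit_did(p, "healthy", c("urrbmi", "lnpcincome", "age")))
    w <- within_fit(p, "healthy", c("urrbmi", "lnpcincome", "age"),
                    "city_id", "year")
    expect_equal(unname(f$coefficients[c("urrbmi", "lnpcincome", "age")]),
                 unname(w), tolerance = 1e-8)
  }
})

test_that("robust and clustered standard errors are both available", {
  p <- small_panel(seed = 9, n = 600, cities = 10)
  fr <- fit_did(p, "healthy", c("urrbmi", "age", "lnpcincome"))
  fc <- fit_did(p, "healthy", c("urrbmi", "age", "lnpcincome"),
                se_type = "cluster")
  expect_identical(fr$coefficients, fc$coefficients)
  expect_false(isTRUE(all.equal(fr$standard_errors[["urrbmi"]],
                                fc$standard_errors[["urrbmi"]])))
  expect_gt(fc$standard_errors[["urrbmi"]], 0)
})

test_that("income quartiles cut on pooled quantiles with ties to the lower quartile", {
  set.seed(5)
  d <- data.frame(lnpcincome = 1:40, treat = rep(c(0, 1), 20),
                  y = rnorm(40))
  out <- fit_by_income_quartile(d, "y", "treat", fe = NULL)
  expect_equal(unname(attr(out, "n")), rep(10L, 4))
  expect_true(all(vapply(out, inherits, logical(1), "did_fit")))

  # 0..20: the 25% quantile is exactly 5; that observation stays in Q1
  d2 <- data.frame(lnpcincome = 0:20, treat = rep_len(c(0, 1), 21),
                   y = rnorm(21))
  out2 <- fit_by_income_quartile(d2, "y", "treat", fe = NULL)
  expect_equal(unname(attr(out2, "n")), c(6L, 5L, 5L, 5L))

  # a quartile whose treatment is constant is flagged, others still fit
  d3 <- d
  d3$treat[d3$lnpcincome <= 10] <- 0
  out3 <- fit_by_income_quartile(d3, "y", "treat", fe = NULL)
  expect_s3_class(out3$Q1, "did_inestimable")
  expect_s3_class(out3$Q4, "did_fit")
})

test_that("a configured expense-effect gradient is recovered across quartiles", {
  # the generator makes the (negative) expense effect strongest in the
  # poorest quartile; average estimates over seeds must be ordered
  q1 <- q4 <- numeric(20)
  for (s in 1:20) {
    p <- small_panel_treated(seed = 100 + s, n = 1200, cities = 10)
    fits <- suppressWarnings(
      fit_by_income_quartile(p, "lnoutself", FULL_FACTORS, fe = NULL))
    q1[s] <- if (inherits(fits$Q1, "did_fit"))
      fits$Q1$coefficients[["urrbmi"]] else NA
    q4[s] <- if (inherits(fits$Q4, "did_fit"))
      fits$Q4$coefficients[["urrbmi"]] else NA
  }
  expect_lt(mean(q1, na.rm = TRUE), mean(q4, na.rm = TRUE))
  expect_lt(mean(q1, na.rm = TRUE), -0.8)  # near the configured Q1 effect
})

test_that("robust tests reject a true null at close to the nominal 5% rate", {
  rejections <- vapply(1:150, function(s) {
    f <- NULL
    for (off in c(0L, 50000L, 100000L)) {  # skip draws with no adopters
      cfg <- config_with_effect("healthy", 0, seed = 300 + s + off,
                                n = 1200, cities = 10)
      p <- generate_panel(cfg)
      f <- tryCatch(suppressWarnings(fit_did(p, "healthy", FULL_FACTORS)),
                    error = function(e) NULL)
      if (!is.null(f)) break
    }
    abs(f$coefficients[["urrbmi"]] / f$standard_errors[["urrbmi"]]) > 1.96
  }, logical(1))
  rate <- mean(rejections)
  # within 3 binomial standard errors of the nominal level
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 150))
})
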