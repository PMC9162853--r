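test_that("configuration is validated", {
  expect_error(synthetic_config(waves = c(2014, 2012, 2016)),
               "strictly increasing")
  expect_error(synthetic_config(n_cities = 1), "at least 2")
  expect_error(synthetic_config(n_individuals = 5, n_cities = 10),
               "at least 'n_cities'")
  expect_error(synthetic_config(coverage_by_wave = c(0.3, 0.2, 0.1)),
               "non-decreasing")
  expect_error(synthetic_config(coverage_by_wave = c(0.1, 0.2, 1.2)),
               "\\[0, 1\\]")
  expect_error(synthetic_config(coverage_by_wave = c(0.1, 0.3, 0.6),
                                adoption_power = 2),
               "probability > 1")
})

test_that("generated panels are deterministic and satisfy the schema invariants", {
  cfg <- synthetic_config(n_individuals = 400, n_cities = 8, seed = 11)
  p1 <- generate_panel(cfg)
  p2 <- generate_panel(cfg)
  attr(p1, "truth") <- attr(p2, "truth") <- NULL
  expect_identical(p1, p2)

  p <- generate_panel(synthetic_config(n_individuals = 800, n_cities = 10,
                                       seed = 3))
  expect_equal(p$age2, p$age^2)
  expect_true(all(p$priedu + p$secedu + p$highedu + p$superhigh <= 1))
  # absorbing adoption: treatment never switches off within a city
  by_city <- split(p[order(p$year), c("year", "urrbmi")],
                   p$city_id[order(p$year)])
  expect_true(all(vapply(by_city, function(d)
    !is.unsorted(tapply(d$urrbmi, d$year, max)), logical(1))))
  # treatment is a city-by-year assignment
  expect_true(all(tapply(p$urrbmi, interaction(p$city_id, p$year),
                         function(v) length(unique(v))) == 1L))
  # expenses observed exactly when the utilization flag is on
  expect_identical(is.na(p$lnoutself), p$outpatient == 0L)
  expect_identical(is.na(p$lnhosself), p$hospital == 0L)
})

test_that("large panels calibrate to the configured study conditions", {
  cfg <- synthetic_config(n_individuals = 20000, seed = 5)
  p <- generate_panel(cfg)
  expect_lt(abs(mean(p$healthy) - 0.557), 0.02)

  # per-wave coverage within 3 s.e. of the targets (city-level assignment)
  cov_w <- tapply(p$urrbmi, p$year, mean)
  for (j in seq_along(cfg$waves)) {
    tgt <- cfg$coverage_by_wave[j]
    se <- sqrt(tgt * (1 - tgt) / cfg$n_cities)
    expect_lt(abs(cov_w[[j]] - tgt), 3 * se)
  }

  # wealth-increasing adoption yields pro-rich coverage inequality
  expect_gt(concentration_index(p$urrbmi, p$lnpcincome)$value, 0)
  city_income <- tapply(p$lnpcincome, p$city_id, mean)
  city_adopted <- tapply(p$urrbmi, p$city_id, max)
  expect_gt(cor(city_income, city_adopted[names(city_income)]), 0)

  # income distribution has the configured location and spread (the city
  # random effect moves the sample mean by ~0.5/sqrt(n_cities))
  expect_lt(abs(mean(p$lnpcincome) - 8.642), 0.25)
  expect_lt(abs(sd(p$lnpcincome) - 1.593), 0.08)
})

test_that("a null policy effect is not detected by the DID fit", {
  cfg <- config_with_effect("healthy", 0, seed = 21, n = 2500, cities = 15)
  p <- generate_panel(cfg)
  f <- suppressWarnings(fit_did(p, "healthy", FULL_FACTORS))
  est <- f$coefficients[["urrbmi"]]
  se <- f$standard_errors[["urrbmi"]]
  expect_lt(abs(est), 1.96 * se)
})

test_that("filter_panel applies rules sequentially and accounts for drops", {
  d <- data.frame(city_id = rep(c("A", "B", "C"), each = 4),
                  x = c(1, NA, 3, 4, 5, 6, NA, 8, 9, 10, 11, 12),
                  y = 1:12)
  # missing-value rule on a 12-row toy with 2 incomplete rows
  out <- filter_panel(d, list(complete = rule_complete("x")))
  expect_equal(nrow(out), 10)
  expect_equal(attr(out, "drop_counts")[["complete"]], 2L)
  # empty rule set is the identity
  expect_equal(nrow(filter_panel(d)), 12)
  # excluding a listed city
  out <- filter_panel(d, list(no_A = "!(city_id %in% c('A'))"))
  expect_equal(nrow(out), 8)
  expect_true(all(out$city_id != "A"))
  # sequential accounting: second rule only counts rows still present
  out <- filter_panel(d, list(no_A = "city_id != 'A'",
                              complete = rule_complete("x")))
  expect_equal(unname(attr(out, "drop_counts")), c(4L, 1L))
  expect_error(filter_panel(d, list(bad = "zzz > 1")), "unknown column")
})
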