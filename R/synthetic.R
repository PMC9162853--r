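#' Default outcome-generating coefficients
#'
#' True coefficients used by [generate_panel()] for each outcome, on the
#' scale of a linear probability model for the binary outcomes and of a
#' linear model for log expenses.  Values sit in the neighbourhood of
#' estimates typically reported for a staggered residents' insurance
#' integration: a small positive effect of coverage on self-rated health
#' (+0.0243) and on utilization, and a large negative effect on log
#' out-of-pocket expense conditional on use.
#'
#' @return Named list (one element per outcome) of named coefficient
#'   vectors.  The policy indicator is `urrbmi`.
#' @export
default_outcome_coefficients <- function() {
  covars <- c("age", "age2", "male", "married", "hhnum", "lnpcincome",
              "rural", "priedu", "secedu", "highedu", "superhigh",
              "pension", "sanitary")
  mk <- function(urrbmi, v) c(urrbmi = urrbmi, stats::setNames(v, covars))
  list(
    healthy = mk(0.0243, c(-0.0210, 0.0001, 0.0606, 0.0685, 0.0012,
                           0.0367, 0.0135, 0.0672, 0.1224, 0.1684,
                           0.3003, 0.0229, 0.0205)),
    outpatient = mk(0.0246, c(0.0039, -0.00004, -0.0268, -0.0212, 0.0007,
                              -0.0058, 0.0051, -0.0174, -0.0293, -0.0276,
                              0.0194, 0.0038, -0.0106)),
    hospital = mk(0.0278, c(-0.0013, 0.00003, -0.0214, 0.0126, 0.0000,
                            -0.0072, -0.0024, -0.0095, -0.0126, -0.0147,
                            -0.0122, 0.0034, -0.0027)),
    lnoutself = mk(-1.0740, c(0.0266, -0.0005, 0.3602, 0.3321, -0.2950,
                              0.0433, 0.0128, -0.6758, -0.6956, -0.8669,
                              1.8758, -0.1324, -0.3828)),
    lnhosself = mk(-0.4289, c(0.0502, -0.0007, 0.2829, 0.1025, -0.1597,
                              0.0752, -0.5041, -0.1403, -0.6857, -0.3383,
                              -0.2324, -0.0194, -0.3301))
  )
}

#' Configuration for the synthetic survey panel
#'
#' Describes a multi-wave household survey with individuals nested in
#' cities and a staggered city-level insurance rollout whose adoption
#' probability rises with city wealth.  Defaults emulate the study
#' conditions the package is designed around: three waves two years
#' apart, right-skewed income (log-normal with a city random effect),
#' covariate means matching a national labour-force survey, coverage
#' rising roughly 0.10 to 0.27 across waves, and a pooled "pro-rich"
#' coverage concentration index of about 0.10.
#'
#' @param n_individuals Number of persons; each appears in every wave.
#' @param n_cities Number of cities (>= 2, <= `n_individuals`).
#' @param waves Strictly increasing survey years.
#' @param seed RNG seed; identical configs generate identical panels.
#' @param coverage_by_wave Target population coverage of the policy at
#'   each wave (non-decreasing, in \[0,1\]; adoption is absorbing).
#' @param adoption_power Steepness of the adoption model: a city at
#'   wealth percentile \eqn{p} adopts by wave \eqn{j} with probability
#'   \eqn{q_j (a+1) p^a} where \eqn{q_j} is the coverage target and
#'   \eqn{a} this power.  `a = 0` makes adoption wealth-neutral; the
#'   default `a = 1` yields a pooled coverage CI near 0.10.
#' @param income_params Log-income components: overall location `mu`,
#'   city random-effect s.d. `sd_city`, persistent person s.d.
#'   `sd_person`, transient wave s.d. `sd_wave`.
#' @param outcome_coefficients Named list of true coefficient vectors,
#'   see [default_outcome_coefficients()].
#' @param target_means Calibration targets for outcome means; the latent
#'   index intercept of each outcome is set so the generated mean matches.
#' @param noise_sd Residual s.d. of the log-expense outcomes.
#' @param expense_quartile_gradient Per-expense-outcome gradient of the
#'   policy effect across pooled income quartiles: the effect in quartile
#'   q is `coef + gradient * (q - 2.5)`, so a positive gradient makes a
#'   negative expense effect strongest (most negative) for the poorest
#'   quartile.  Set to 0 for a uniform effect.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_individuals = 20000,
                             n_cities = 60,
                             waves = c(2012, 2014, 2016),
                             seed = 1,
                             coverage_by_wave = c(0.0985, 0.1479, 0.2717),
                             adoption_power = 1,
                             income_params = list(mu = 8.642, sd_city = 0.5,
                                                  sd_person = 1.0,
                                                  sd_wave = 1.105),
                             outcome_coefficients = default_outcome_coefficients(),
                             target_means = c(healthy = 0.557,
                                              outpatient = 0.087,
                                              hospital = 0.081,
                                              lnoutself = 4.246,
                                              lnhosself = 6.836),
                             noise_sd = c(lnoutself = 2.70, lnhosself = 2.85),
                             expense_quartile_gradient = c(lnoutself = 0.25,
                                                           lnhosself = 0.25)) {
  if (n_cities < 2) stop("'n_cities' must be at least 2")
  if (n_individuals < n_cities) {
    stop("'n_individuals' must be at least 'n_cities'")
  }
  if (length(waves) < 1L || is.unsorted(waves, strictly = TRUE)) {
    stop("'waves' must be strictly increasing")
  }
  if (length(coverage_by_wave) != length(waves)) {
    stop("'coverage_by_wave' must have one entry per wave")
  }
  if (any(coverage_by_wave < 0) || any(coverage_by_wave > 1)) {
    stop("coverage targets must lie in [0, 1]")
  }
  if (is.unsorted(coverage_by_wave)) {
    stop("coverage targets must be non-decreasing (adoption is absorbing)")
  }
  if (adoption_power < 0) stop("'adoption_power' must be non-negative")
  # adoption probabilities q_j * (a+1) p^a must stay within [0, 1]
  if (max(coverage_by_wave) * (adoption_power + 1) > 1 + 1e-12) {
    stop("adoption model assigns probability > 1 to the wealthiest city; ",
         "lower 'adoption_power' or the coverage targets")
  }
  for (nm in names(outcome_coefficients)) {
    if (!"urrbmi" %in% names(outcome_coefficients[[nm]])) {
      stop(sprintf("coefficients for '%s' lack a 'urrbmi' entry", nm))
    }
  }
  structure(
    list(n_individuals = as.integer(n_individuals),
         n_cities = as.integer(n_cities),
         waves = as.integer(waves), seed = as.integer(seed),
         coverage_by_wave = coverage_by_wave,
         adoption_power = adoption_power,
         income_params = income_params,
         outcome_coefficients = outcome_coefficients,
         target_means = target_means, noise_sd = noise_sd,
         expense_quartile_gradient = expense_quartile_gradient),
    class = "synthetic_config"
  )
}

# covariate distribution constants (survey-like means):
# education split renormalised to sum to one; shifts feed log income so
# better-educated respondents rank higher.
.edu_probs <- local({
  p <- c(illit = 0.171, priedu = 0.628, secedu = 0.124,
         highedu = 0.037, superhigh = 0.001)
  p / sum(p)
})
.edu_income_shift <- c(illit = -0.40, priedu = -0.05, secedu = 0.35,
                       highedu = 0.70, superhigh = 1.20)

#' Generate a synthetic survey panel
#'
#' Draws a balanced individual-by-wave panel under a known
#' data-generating process: city wealth effects order cities, a
#' wealth-indexed categorical assigns each city an (absorbing) adoption
#' wave, log income combines city, person, education and transient
#' components, binary outcomes are Bernoulli with linear probabilities
#' (so the linear probability model is well-specified and the configured
#' coefficients are recoverable), and log expenses are Gaussian
#' conditional on the corresponding utilization flag.  Intercepts are
#' calibrated so realised outcome means match the configured targets.
#'
#' @param config A [synthetic_config()].
#' @return A data frame of class `panel_dataset` with one row per person
#'   and wave; columns `person_id`, `city_id`, `year`, `urrbmi`,
#'   `lnpcincome`, the five outcomes, and the demographic covariates.
#'   Log-expense columns are `NA` when the matching utilization flag is
#'   0.  The true parameters are attached as `attr(, "truth")`.
#' @export
generate_panel <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    stop("'config' must be created by synthetic_config()")
  }
  set.seed(config$seed)
  nc <- config$n_cities
  ni <- config$n_individuals
  waves <- config$waves
  W <- length(waves)
  ip <- config$income_params

  ## cities: wealth effect, wealth percentile, east region, adoption wave
  city_eff <- stats::rnorm(nc, 0, ip$sd_city)
  p_c <- (rank(city_eff) - 0.5) / nc
  east_c <- stats::runif(nc) < pmin(pmax(0.353 + 0.6 * (p_c - 0.5), 0), 1)
  wgt <- (config$adoption_power + 1) * p_c^config$adoption_power
  u_c <- stats::runif(nc)
  adopt_wave <- rep(Inf, nc)
  for (j in rev(seq_len(W))) {
    adopt_wave[u_c < config$coverage_by_wave[j] * wgt] <- j
  }

  ## persons
  city <- sample.int(nc, ni, replace = TRUE)
  base_age <- pmin(pmax(stats::rnorm(ni, 43.6, 14.56), 15), 60)
  male <- as.integer(stats::runif(ni) < 0.473)
  married <- as.integer(stats::runif(ni) < 0.831)
  pension <- as.integer(stats::runif(ni) < 0.521)
  sanitary <- as.integer(stats::runif(ni) < 0.849)
  hhnum <- 1L + stats::rpois(ni, 2.961)
  p_rural <- pmin(pmax(0.89 + 0.15 * (0.5 - p_c[city]), 0), 1)
  rural <- as.integer(stats::runif(ni) < p_rural)
  edu <- sample.int(5L, ni, replace = TRUE, prob = .edu_probs)
  edu_d <- outer(edu, 2:5, `==`) * 1L  # illiterate is the omitted level
  colnames(edu_d) <- c("priedu", "secedu", "highedu", "superhigh")
  person_inc <- stats::rnorm(ni, 0, ip$sd_person) +
    .edu_income_shift[edu] - sum(.edu_probs * .edu_income_shift) -
    0.2 * (rural - 0.89)

  ## long panel
  idx <- rep(seq_len(ni), times = W)
  wv <- rep(seq_len(W), each = ni)
  N <- ni * W
  year <- waves[wv]
  age <- base_age[idx] + (year - waves[1L])
  lnpcincome <- ip$mu + city_eff[city[idx]] + person_inc[idx] +
    stats::rnorm(N, 0, ip$sd_wave)
  urrbmi <- as.integer(wv >= adopt_wave[city[idx]])

  qs <- stats::quantile(lnpcincome, c(0.25, 0.5, 0.75), names = FALSE)
  quartile <- 1L + (lnpcincome > qs[1]) + (lnpcincome > qs[2]) +
    (lnpcincome > qs[3])

  X <- cbind(age = age, age2 = age^2, male = male[idx],
             married = married[idx], hhnum = hhnum[idx],
             lnpcincome = lnpcincome, rural = rural[idx],
             edu_d[idx, , drop = FALSE],
             pension = pension[idx], sanitary = sanitary[idx])

  draw_binary <- function(coefs, target) {
    covars <- setdiff(names(coefs), "urrbmi")
    index <- drop(X[, covars, drop = FALSE] %*% coefs[covars]) +
      coefs[["urrbmi"]] * urrbmi
    p <- (target - mean(index)) + index
    clipped <- mean(p < 0 | p > 1)
    y <- as.integer(stats::runif(N) < pmin(pmax(p, 0), 1))
    list(y = y, clipped = clipped)
  }
  draw_expense <- function(coefs, target, sd, gradient, flag) {
    covars <- setdiff(names(coefs), "urrbmi")
    eff <- coefs[["urrbmi"]] + gradient * (quartile - 2.5)
    index <- drop(X[, covars, drop = FALSE] %*% coefs[covars]) + eff * urrbmi
    on <- flag == 1L
    out <- rep(NA_real_, N)
    out[on] <- (target - mean(index[on])) + index[on] +
      stats::rnorm(sum(on), 0, sd)
    out
  }

  oc <- config$outcome_coefficients
  tm <- config$target_means
  healthy <- draw_binary(oc$healthy, tm[["healthy"]])
  outpatient <- draw_binary(oc$outpatient, tm[["outpatient"]])
  hospital <- draw_binary(oc$hospital, tm[["hospital"]])
  lnoutself <- draw_expense(oc$lnoutself, tm[["lnoutself"]],
                            config$noise_sd[["lnoutself"]],
                            config$expense_quartile_gradient[["lnoutself"]],
                            outpatient$y)
  lnhosself <- draw_expense(oc$lnhosself, tm[["lnhosself"]],
                            config$noise_sd[["lnhosself"]],
                            config$expense_quartile_gradient[["lnhosself"]],
                            hospital$y)

  panel <- data.frame(
    person_id = idx, city_id = city[idx], year = year, urrbmi = urrbmi,
    lnpcincome = lnpcincome, healthy = healthy$y,
    outpatient = outpatient$y, hospital = hospital$y,
    lnoutself = lnoutself, lnhosself = lnhosself,
    age = age, age2 = age^2, male = male[idx], married = married[idx],
    hhnum = hhnum[idx], rural = rural[idx], edu_d[idx, , drop = FALSE],
    pension = pension[idx], sanitary = sanitary[idx],
    east = as.integer(east_c[city[idx]])
  )
  attr(panel, "truth") <- list(
    coefficients = oc,
    expense_quartile_gradient = config$expense_quartile_gradient,
    adoption = data.frame(city_id = seq_len(nc), wealth_percentile = p_c,
                          adopt_wave = adopt_wave),
    clip_rate = c(healthy = healthy$clipped, outpatient = outpatient$clipped,
                  hospital = hospital$clipped),
    config = config
  )
  class(panel) <- c("panel_dataset", "data.frame")
  panel
}

#' Filter a panel with named row rules
#'
#' Applies a sequence of row predicates (generic analogues of survey
#' cleaning steps such as dropping other insurance schemes, excluding
#' listed cities, or removing incomplete records) and reports how many
#' rows each rule removed.
#'
#' @param data A data frame.
#' @param rules Named list (or character vector) of filter expressions,
#'   each a string parsed and evaluated within `data`; rows where the
#'   expression is `TRUE` are kept.  `NA` evaluations drop the row.
#'   Every variable referenced must be a column of `data`.
#' @return The filtered data frame with attribute `drop_counts`, a named
#'   integer vector of rows dropped by each rule (applied in order).
#' @seealso [rule_complete()] for a non-missingness rule.
#' @examples
#' d <- data.frame(city_id = c("A", "B", "B"), x = c(1, NA, 3))
#' filter_panel(d, list(no_A = "city_id != 'A'", complete = rule_complete("x")))
#' @export
filter_panel <- function(data, rules = list()) {
  stopifnot(is.data.frame(data))
  rules <- as.list(rules)
  if (length(rules) > 0L && is.null(names(rules))) {
    names(rules) <- paste0("rule", seq_along(rules))
  }
  keep <- rep(TRUE, nrow(data))
  counts <- stats::setNames(integer(length(rules)), names(rules))
  for (nm in names(rules)) {
    expr <- str2lang(rules[[nm]])
    assert_columns(data, all.vars(expr))
    ok <- eval(expr, data, baseenv())
    if (!is.logical(ok) || !length(ok) %in% c(1L, nrow(data))) {
      stop(sprintf("rule '%s' must evaluate to a logical row predicate", nm))
    }
    ok <- rep_len(ok, nrow(data))
    ok[is.na(ok)] <- FALSE
    counts[nm] <- sum(keep & !ok)
    keep <- keep & ok
  }
  out <- data[keep, , drop = FALSE]
  attr(out, "drop_counts") <- counts
  out
}

#' Rule keeping rows complete on the given columns
#'
#' @param cols Character vector of column names.
#' @return A filter expression string for [filter_panel()].
#' @export
rule_complete <- function(cols) {
  paste(sprintf("!is.na(%s)", cols), collapse = " & ")
}

#' @export
print.panel_dataset <- function(x, ...) {
  cat(sprintf("Synthetic survey panel: %d rows (%d persons x %d waves), %d cities\n",
              nrow(x), length(unique(x$person_id)), length(unique(x$year)),
              length(unique(x$city_id))))
  NextMethod()
}
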