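#' Two-way fixed-effects (time-varying DID) regression
#'
#' Fits \eqn{y_{ict} = \alpha + \beta T_{ct} + X_{ict}'\theta + \mu_c +
#' \vartheta_t + \varepsilon_{ict}} by OLS with explicit city and year
#' dummies, where the treatment indicator switches on at city-specific
#' adoption times.  Binary outcomes are fit as linear probability models
#' so the coefficients feed directly into the Wagstaff decomposition.
#' Standard errors are heteroskedasticity-robust (HC1) by default, or
#' clustered on a grouping column.
#'
#' The first element of `factors` is treated as the policy variable of
#' interest: if it is constant in the estimation sample the fit aborts
#' with an error, whereas other factors without variation are dropped
#' with a warning.  Collinear columns (including redundant fixed-effect
#' dummies) are likewise dropped with a warning.
#'
#' @param data Data frame (e.g. a `panel_dataset`).
#' @param outcome Name of the outcome column.  Rows with missing values
#'   in the outcome or any regressor are dropped, so log-expense
#'   outcomes are automatically fit conditional on use.
#' @param factors Character vector of regressor columns; the first is
#'   the treatment/policy indicator.
#' @param fe Character vector of columns absorbed as fixed-effect
#'   dummies (default city and year); `NULL` for none.
#' @param se_type `"robust"` (HC1) or `"cluster"`.
#' @param cluster Clustering column used when `se_type = "cluster"`.
#' @return Object of class `did_fit` with elements `coefficients` and
#'   `standard_errors` (intercept and factors), `all_coefficients` /
#'   `all_standard_errors` (including fixed-effect dummies),
#'   `residuals`, `r_squared`, `n_obs`, `df_residual`, `fixed_effects`
#'   (levels absorbed per dimension), `outcome_name`, `outcome_mean`,
#'   `factors`, `used_rows` (row indices of `data` in the estimation
#'   sample) and `dropped_terms`.
#' @examples
#' cfg <- synthetic_config(n_individuals = 600, n_cities = 8, seed = 3)
#' panel <- generate_panel(cfg)
#' fit <- fit_did(panel, "healthy", c("urrbmi", "age", "lnpcincome"))
#' fit$coefficients[["urrbmi"]]
#' @export
fit_did <- function(data, outcome, factors, fe = c("city_id", "year"),
                    se_type = c("robust", "cluster"), cluster = "city_id") {
  se_type <- match.arg(se_type)
  stopifnot(is.data.frame(data), length(factors) >= 1L)
  assert_columns(data, c(outcome, factors, fe,
                         if (se_type == "cluster") cluster))
  cols <- unique(c(outcome, factors, fe, if (se_type == "cluster") cluster))
  used <- which(stats::complete.cases(data[cols]))
  if (length(used) < length(factors) + 2L) stop("too few complete rows")
  d <- data[used, cols, drop = FALSE]

  if (stats::var(d[[outcome]]) == 0) {
    stop(sprintf("outcome '%s' is constant in the estimation sample", outcome))
  }
  keep_factors <- factors
  for (f in factors) {
    if (length(unique(d[[f]])) < 2L) {
      if (f == factors[1L]) {
        stop(sprintf(
          "treatment '%s' has no variation: effect is inestimable", f))
      }
      warning(sprintf("factor '%s' is constant and was dropped", f))
      keep_factors <- setdiff(keep_factors, f)
    }
  }
  fe <- fe[vapply(fe, function(v) length(unique(d[[v]])) > 1L, logical(1))]
  if (length(fe)) {
    # a treatment perfectly explained by the fixed effects (e.g. a
    # city-level indicator in a single wave) is not identified even
    # though lm() would silently drop a dummy instead
    Dfe <- stats::model.matrix(
      stats::reformulate(sprintf("factor(%s)", fe)), data = d)
    rt <- qr.resid(qr(Dfe), d[[factors[1L]]])
    if (sum(rt^2) < 1e-10 * length(rt)) {
      stop(sprintf("treatment '%s' is collinear with the fixed effects: %s",
                   factors[1L], "effect is inestimable"))
    }
  }

  rhs <- c(keep_factors,
           if (length(fe)) sprintf("factor(%s)", fe))
  fml <- stats::reformulate(rhs, response = outcome)
  fit <- stats::lm(fml, data = d)

  cf <- stats::coef(fit)
  aliased <- names(cf)[is.na(cf)]
  if (factors[1L] %in% aliased) {
    stop(sprintf("treatment '%s' is collinear with the fixed effects: %s",
                 factors[1L], "effect is inestimable"))
  }
  if (length(aliased)) {
    warning(sprintf("rank-deficient design; dropped: %s",
                    paste(aliased, collapse = ", ")))
  }
  est <- cf[!is.na(cf)]
  res <- stats::residuals(fit)
  r2 <- 1 - sum(res^2) / sum((d[[outcome]] - mean(d[[outcome]]))^2)
  vc <- if (se_type == "robust") {
    sandwich::vcovHC(fit, type = "HC1")
  } else {
    sandwich::vcovCL(fit, cluster = d[[cluster]])
  }
  se_all <- stats::setNames(sqrt(diag(vc))[names(est)], names(est))

  main <- intersect(c("(Intercept)", keep_factors), names(est))
  fe_levels <- lapply(stats::setNames(fe, fe),
                      function(v) sort(unique(d[[v]])))
  structure(
    list(coefficients = est[main], standard_errors = se_all[main],
         all_coefficients = est, all_standard_errors = se_all,
         residuals = res, r_squared = r2,
         outcome_checksum = sum(d[[outcome]] * seq_along(used)),
         n_obs = length(used), df_residual = fit$df.residual,
         fixed_effects = fe_levels, outcome_name = outcome,
         outcome_mean = mean(d[[outcome]]), factors = keep_factors,
         used_rows = used, dropped_terms = aliased, se_type = se_type),
    class = "did_fit"
  )
}

#' Coefficient table of a DID fit
#'
#' @param fit A `did_fit`.
#' @param all Include fixed-effect dummy rows?
#' @return Data frame with term, estimate, standard error, t statistic,
#'   p-value and significance stars at the 0.10/0.05/0.01 levels.
#' @export
did_table <- function(fit, all = FALSE) {
  stopifnot(inherits(fit, "did_fit"))
  est <- if (all) fit$all_coefficients else fit$coefficients
  se <- if (all) fit$all_standard_errors else fit$standard_errors
  tval <- est / se
  pval <- 2 * stats::pt(abs(tval), df = fit$df_residual, lower.tail = FALSE)
  data.frame(term = names(est), estimate = unname(est),
             std_error = unname(se), statistic = unname(tval),
             p_value = unname(pval), stars = signif_stars(unname(pval)),
             row.names = NULL)
}

#' DID fits by pooled income quartile
#'
#' Cuts the estimation sample into quartiles of the income column using
#' pooled sample quantiles (observations tied at a boundary go to the
#' lower quartile) and refits the DID specification in each, to expose
#' heterogeneity of the policy effect along the income distribution.
#'
#' @inheritParams fit_did
#' @param income Column defining the quartiles (default log per-capita
#'   income).
#' @param ... Passed on to [fit_did()].
#' @return Named list (`Q1`..`Q4`) of `did_fit` objects; a quartile in
#'   which the treatment does not vary (or the fit otherwise fails) is
#'   represented by a `did_inestimable` stub carrying the message.  The
#'   quartile sizes and cut points are attached as attributes.
#' @export
fit_by_income_quartile <- function(data, outcome, factors,
                                   fe = c("city_id", "year"),
                                   income = "lnpcincome", ...) {
  assert_columns(data, income)
  x <- data[[income]]
  qs <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, na.rm = TRUE)
  quart <- 1L + (x > qs[1]) + (x > qs[2]) + (x > qs[3])
  out <- vector("list", 4L)
  names(out) <- paste0("Q", 1:4)
  sizes <- integer(4L)
  for (q in 1:4) {
    sub <- data[which(quart == q), , drop = FALSE]
    sizes[q] <- nrow(sub)
    out[[q]] <- tryCatch(
      fit_did(sub, outcome, factors, fe = fe, ...),
      error = function(e) structure(list(message = conditionMessage(e)),
                                    class = "did_inestimable"))
  }
  attr(out, "n") <- stats::setNames(sizes, names(out))
  attr(out, "breaks") <- qs
  out
}

#' @export
print.did_fit <- function(x, ...) {
  cat(sprintf("Two-way FE regression of '%s' (n = %d, R^2 = %.4f)\n",
              x$outcome_name, x$n_obs, x$r_squared))
  tab <- did_table(x)
  est <- sprintf("%.4f%s (%.4f)", tab$estimate, formatC(tab$stars, width = -3),
                 tab$std_error)
  cat(paste0(format(tab$term, width = 14), est, collapse = "\n"), "\n")
  if (length(x$fixed_effects)) {
    cat(sprintf("Fixed effects: %s\n",
                paste(sprintf("%s (%d levels)", names(x$fixed_effects),
                              lengths(x$fixed_effects)), collapse = ", ")))
  }
  cat(sprintf("Standard errors: %s\n", x$se_type))
  invisible(x)
}

#' @export
print.did_inestimable <- function(x, ...) {
  cat("Inestimable:", x$message, "\n")
  invisible(x)
}
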