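#' Elasticity of an outcome with respect to a factor
#'
#' Evaluated at sample means: \eqn{\eta_k = \rho_k \bar x_k / \bar y},
#' the percentage change in the outcome per 1\% change in the factor.
#' This is the weight a factor's own concentration index receives in the
#' Wagstaff decomposition.
#'
#' @param coefficient Regression coefficient \eqn{\rho_k}.
#' @param factor_mean Sample mean \eqn{\bar x_k}.
#' @param outcome_mean Sample mean \eqn{\bar y}; must be nonzero.
#' @return Numeric (vectorised over the arguments).
#' @examples
#' elasticity(0.0246, 0.1783, 0.0866)   # 0.0506
#' @export
elasticity <- function(coefficient, factor_mean, outcome_mean) {
  if (any(outcome_mean == 0)) stop("'outcome_mean' must be nonzero")
  coefficient * factor_mean / outcome_mean
}

#' Wagstaff decomposition of a concentration index
#'
#' Splits the outcome's concentration index into per-factor
#' contributions \eqn{\eta_k \, CI(x_k|I)} plus a residual:
#' \deqn{CI(y|I) = \sum_k \frac{\rho_k \bar x_k}{\bar y} CI(x_k|I) +
#'   \frac{GC(\varepsilon)}{\bar y},}
#' where \eqn{GC(\varepsilon) = 2\,\mathrm{cov}(\varepsilon, r)} is the
#' generalized concentration index of the regression residual.  Because
#' the regression is linear and index and regression share the sample,
#' the identity holds exactly (to floating-point precision).  The
#' residual is scaled by the outcome mean; this is the scaling under
#' which the identity closes.
#'
#' Fixed-effect dummies are not listed as factors by default; their
#' contribution is absorbed into the residual term, mirroring the usual
#' presentation that tabulates substantive covariates only.  Set
#' `include_fe = TRUE` to list each absorbed dummy as a row, in which
#' case the residual reduces to the pure error-term component.
#'
#' @param fit A [fit_did()] result.
#' @param data The same data frame the fit was produced from.
#' @param income Ranking variable column.
#' @param include_fe List fixed-effect dummies as factor rows?
#' @return Object of class `decomp_table`: `outcome_name`,
#'   `outcome_mean`, `total_ci`, `rows` (data frame with factor,
#'   coefficient, mean, elasticity, factor_ci, contribution,
#'   contribution_rate in percent), `residual_contribution`,
#'   `residual_rate`, `n`.  A factor whose sample mean is zero gets `NA`
#'   elasticity and factor CI but its contribution is still computed
#'   from the generalized concentration index, keeping the identity
#'   exact.
#' @export
wagstaff_decompose <- function(fit, data, income = "lnpcincome",
                               include_fe = FALSE) {
  stopifnot(inherits(fit, "did_fit"), is.data.frame(data))
  assert_columns(data, income)
  if (max(fit$used_rows) > nrow(data)) {
    stop("'data' does not contain the rows the regression was fit on")
  }
  d <- data[fit$used_rows, , drop = FALSE]
  y <- d[[fit$outcome_name]]
  same_mean <- isTRUE(all.equal(mean(y), fit$outcome_mean,
                                tolerance = 1e-12))
  same_sum <- is.null(fit$outcome_checksum) ||
    isTRUE(all.equal(sum(y * seq_along(y)), fit$outcome_checksum,
                     tolerance = 1e-12))
  if (!same_mean || !same_sum) {
    stop("sample mismatch: 'data' differs from the data used in 'fit'")
  }
  r <- fractional_rank(d[[income]])
  ybar <- fit$outcome_mean
  total_ci <- 2 * pop_cov(y, r) / ybar

  one_row <- function(name, x, rho) {
    xbar <- mean(x)
    gc_x <- 2 * pop_cov(x, r)
    ci_x <- if (xbar != 0) gc_x / xbar else NA_real_
    eta <- if (xbar != 0) elasticity(rho, xbar, ybar) else NA_real_
    contribution <- rho * gc_x / ybar
    data.frame(factor = name, coefficient = rho, mean = xbar,
               elasticity = eta, factor_ci = ci_x,
               contribution = contribution,
               contribution_rate = 100 * contribution / total_ci)
  }

  rows <- do.call(rbind, lapply(fit$factors, function(f) {
    rho <- fit$all_coefficients[[f]]
    if (is.null(rho)) return(NULL)  # dropped as collinear
    one_row(f, d[[f]], rho)
  }))
  if (include_fe) {
    for (fe_var in names(fit$fixed_effects)) {
      lv <- fit$fixed_effects[[fe_var]]
      for (l in lv[-1L]) {  # first level is the reference
        nm <- sprintf("factor(%s)%s", fe_var, l)
        rho <- fit$all_coefficients[[nm]]
        if (is.null(rho)) next
        rows <- rbind(rows, one_row(nm, as.numeric(d[[fe_var]] == l), rho))
      }
    }
  }
  residual <- total_ci - sum(rows$contribution)
  structure(
    list(outcome_name = fit$outcome_name, outcome_mean = ybar,
         total_ci = total_ci, rows = rows,
         residual_contribution = residual,
         residual_rate = 100 - sum(rows$contribution_rate),
         error_gci = 2 * pop_cov(fit$residuals, r) / ybar,
         n = fit$n_obs, include_fe = include_fe),
    class = "decomp_table"
  )
}

#' Assemble a decomposition table from known quantities
#'
#' Constructor for a `decomp_table` from externally supplied per-factor
#' numbers (for instance a published decomposition table), so that the
#' change-decomposition tools can be applied to them.  Missing derivable
#' columns are filled in: elasticity from coefficient, mean and outcome
#' mean; contribution as elasticity times factor CI; contribution rate
#' relative to the total CI.
#'
#' @param outcome_name Outcome label.
#' @param outcome_mean Sample mean of the outcome.
#' @param total_ci The outcome's concentration index.
#' @param rows Data frame with column `factor` plus any of
#'   `coefficient`, `mean`, `elasticity`, `factor_ci`, `contribution`,
#'   `contribution_rate`.
#' @param n Sample size (optional).
#' @return A `decomp_table`.
#' @export
decomposition_table <- function(outcome_name, outcome_mean, total_ci, rows,
                                n = NA_integer_) {
  stopifnot(is.data.frame(rows), "factor" %in% names(rows))
  for (cl in c("coefficient", "mean", "elasticity", "factor_ci",
               "contribution", "contribution_rate")) {
    if (!cl %in% names(rows)) rows[[cl]] <- NA_real_
  }
  fill <- is.na(rows$elasticity)
  rows$elasticity[fill] <- elasticity(rows$coefficient[fill],
                                      rows$mean[fill], outcome_mean)
  fill <- is.na(rows$contribution)
  rows$contribution[fill] <- rows$elasticity[fill] * rows$factor_ci[fill]
  fill <- is.na(rows$contribution_rate)
  rows$contribution_rate[fill] <- 100 * rows$contribution[fill] / total_ci
  structure(
    list(outcome_name = outcome_name, outcome_mean = outcome_mean,
         total_ci = total_ci, rows = rows,
         residual_contribution = total_ci - sum(rows$contribution),
         residual_rate = 100 - sum(rows$contribution_rate),
         error_gci = NA_real_, n = n, include_fe = FALSE),
    class = "decomp_table"
  )
}

#' @export
print.decomp_table <- function(x, digits = 4, ...) {
  cat(sprintf("Wagstaff decomposition of CI(%s) = %.4f (mean %.4f, n = %s)\n",
              x$outcome_name, x$total_ci, x$outcome_mean,
              format(x$n, big.mark = ",")))
  tab <- x$rows
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, digits)
  print(tab, row.names = FALSE)
  cat(sprintf("Residual: %.4f (%.2f%%)\n",
              x$residual_contribution, x$residual_rate))
  invisible(x)
}

#' Export a decomposition table as CSV
#'
#' Writes the per-factor rows plus a residual row, numbers rounded to 4
#' decimals and rates to 2, matching the conventional table layout.
#'
#' @param x A `decomp_table`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_decomp_csv <- function(x, path) {
  stopifnot(inherits(x, "decomp_table"))
  tab <- x$rows
  tab <- rbind(tab, data.frame(factor = "residual", coefficient = NA,
                               mean = NA, elasticity = NA, factor_ci = NA,
                               contribution = x$residual_contribution,
                               contribution_rate = x$residual_rate))
  for (cl in c("coefficient", "mean", "elasticity", "factor_ci",
               "contribution")) {
    tab[[cl]] <- round(tab[[cl]], 4)
  }
  tab$contribution_rate <- round(tab$contribution_rate, 2)
  utils::write.csv(cbind(outcome = x$outcome_name, tab), path,
                   row.names = FALSE, na = "")
  invisible(path)
}
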