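#' Fractional income ranks
#'
#' Midpoint fractional ranks of a socioeconomic (income) variable, the
#' ranking variable against which concentration indices are computed.
#' Observation \eqn{i} receives \eqn{r_i = (R_i - 0.5)/n} where \eqn{R_i}
#' is its positional rank in the income ordering; tied incomes receive the
#' average of their positional ranks, so the unweighted ranks always
#' average exactly 0.5.
#'
#' @param income Numeric vector of the living-standards/ranking variable
#'   (e.g. log household income per capita).  Must be nonempty and free of
#'   missing values.
#' @param weights Optional positive sampling weights.  Weighted ranks are
#'   the cumulative weight up to the midpoint of each observation's weight
#'   band, averaged within tied-income groups; they average 0.5 under the
#'   weight distribution.
#' @return Numeric vector of ranks in (0, 1).
#' @examples
#' fractional_rank(c(10, 20, 30))   # 1/6, 1/2, 5/6
#' fractional_rank(c(5, 5, 9))      # ties share the average rank
#' @export
fractional_rank <- function(income, weights = NULL) {
  if (length(income) == 0L) stop("'income' must be a nonempty vector")
  if (anyNA(income)) stop("'income' contains missing values")
  n <- length(income)
  if (is.null(weights)) {
    return((rank(income, ties.method = "average") - 0.5) / n)
  }
  if (length(weights) != n) stop("'weights' must match 'income' in length")
  if (anyNA(weights) || any(weights <= 0)) stop("'weights' must be positive")
  w <- weights / sum(weights)
  ord <- order(income)
  ws <- w[ord]
  r_sorted <- cumsum(ws) - ws / 2
  grp <- cumsum(c(TRUE, diff(income[ord]) > 0))
  num <- tapply(r_sorted * ws, grp, sum)
  den <- tapply(ws, grp, sum)
  out <- numeric(n)
  out[ord] <- (num / den)[grp]
  out
}

#' Concentration index by the convenient covariance formula
#'
#' The concentration index of an outcome with respect to income rank:
#' \deqn{CI = \frac{2\,\mathrm{cov}(y, r)}{\bar y},}
#' where \eqn{r} is the midpoint fractional income rank and the covariance
#' uses the population (divisor \eqn{n}) convention.  Positive values mean
#' the outcome is concentrated among higher-income individuals
#' ("pro-rich"); for a burden-type outcome such as out-of-pocket expense a
#' positive index means the burden falls on the rich.  Equivalently the
#' index is one minus twice the area under the concentration curve; see
#' [concentration_curve()] and [ci_from_curve()], which agree with this
#' formula to numerical precision under the same divisor convention.
#'
#' @param y Outcome vector (binary indicators are used as-is; no
#'   normalisation for bounded outcomes is applied).
#' @param income Ranking variable, same length as `y`.
#' @param weights Optional positive sampling weights.
#' @param outcome_name Label stored in the result.
#' @return An object of class `ci_result`: list with elements `value`,
#'   `outcome_name`, `mean_outcome`, `n`, `method`.
#' @examples
#' inc <- 1:5
#' r <- fractional_rank(inc)
#' concentration_index(r, inc)$value  # 0.32
#' @export
concentration_index <- function(y, income, weights = NULL,
                                outcome_name = deparse(substitute(y))) {
  if (length(y) != length(income)) {
    stop("'y' and 'income' must have the same length")
  }
  if (length(y) == 0L) stop("empty input")
  if (anyNA(y) || anyNA(income)) stop("missing values in 'y' or 'income'")
  mu <- wtd_mean(y, weights)
  if (mu == 0) {
    stop("concentration index undefined: outcome mean is zero")
  }
  if (any(y < 0)) {
    warning("negative outcome values: |CI| is not bounded by 1")
  }
  r <- fractional_rank(income, weights)
  value <- 2 * pop_cov(y, r, weights) / mu
  structure(
    list(value = value, outcome_name = outcome_name, mean_outcome = mu,
         n = length(y), method = "covariance"),
    class = "ci_result"
  )
}

#' Concentration curve
#'
#' Cumulative outcome share against the cumulative population share ranked
#' by income.  Tied incomes are pooled into a single segment so the curve
#' does not depend on their arbitrary ordering; the piecewise-linear curve
#' then reproduces the covariance-formula index exactly through
#' [ci_from_curve()].
#'
#' @inheritParams concentration_index
#' @return Object of class `concentration_curve`: list with `points` (a
#'   data frame of `q`, cumulative rank fraction, and `C`, cumulative
#'   outcome share, starting at (0,0) and ending at (1,1)) and `n`.
#' @export
concentration_curve <- function(y, income) {
  if (length(y) != length(income)) {
    stop("'y' and 'income' must have the same length")
  }
  if (length(y) == 0L) stop("empty input")
  if (anyNA(y) || anyNA(income)) stop("missing values in 'y' or 'income'")
  total <- sum(y)
  if (total <= 0) stop("total outcome must be positive to draw a curve")
  ord <- order(income)
  ys <- y[ord]
  grp <- cumsum(c(TRUE, diff(income[ord]) > 0))
  n <- length(y)
  n_g <- tabulate(grp)
  y_g <- as.numeric(tapply(ys, grp, sum))
  pts <- data.frame(
    q = c(0, cumsum(n_g) / n),
    C = c(0, cumsum(y_g) / total)
  )
  structure(list(points = pts, n = n), class = "concentration_curve")
}

#' Concentration index from a concentration curve
#'
#' One minus twice the trapezoid area under the piecewise-linear curve.
#' Cross-check oracle for [concentration_index()]; the two agree to
#' numerical precision because both use the divisor-n convention and tied
#' incomes are pooled.
#'
#' @param curve A `concentration_curve`.
#' @return Numeric scalar.
#' @export
ci_from_curve <- function(curve) {
  stopifnot(inherits(curve, "concentration_curve"))
  q <- curve$points$q
  C <- curve$points$C
  area <- sum(diff(q) * (C[-1] + C[-length(C)]) / 2)
  1 - 2 * area
}

#' @export
as.data.frame.concentration_curve <- function(x, ...) x$points

#' @export
print.ci_result <- function(x, ...) {
  cat(sprintf("Concentration index of %s: %.4f\n", x$outcome_name, x$value))
  cat(sprintf("  mean outcome %.4f on n = %d (%s formula)\n",
              x$mean_outcome, x$n, x$method))
  invisible(x)
}

#' @export
print.concentration_curve <- function(x, ...) {
  cat(sprintf("Concentration curve on n = %d (%d points)\n",
              x$n, nrow(x$points)))
  cat(sprintf("  implied CI = %.4f\n", ci_from_curve(x)))
  invisible(x)
}
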