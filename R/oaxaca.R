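#' Per-wave regression and decomposition tables
#'
#' Refits the factor regression independently in each survey wave and
#' runs the Wagstaff decomposition on the wave's own sample and income
#' ranking, yielding year-specific coefficients, means, elasticities and
#' factor concentration indices.  Because a city-level treatment is
#' constant within a city in a single wave, city fixed effects would
#' absorb it; the per-wave fits therefore default to no fixed effects
#' (the cross-sectional factor regression).
#'
#' @inheritParams fit_did
#' @param income Ranking column.
#' @param periods Years to fit (default: all years present, sorted).
#' @param year_col Column holding the survey year.
#' @param ... Passed to [fit_did()].
#' @return Named list (one element per year) of `decomp_table`s; a wave
#'   where the fit is impossible (e.g. constant treatment) holds a
#'   `did_inestimable` stub instead.
#' @export
per_period_tables <- function(data, outcome, factors, income = "lnpcincome",
                              periods = NULL, fe = NULL,
                              year_col = "year", ...) {
  assert_columns(data, year_col)
  periods <- periods %||% sort(unique(data[[year_col]]))
  out <- stats::setNames(vector("list", length(periods)),
                         as.character(periods))
  for (p in as.character(periods)) {
    sub <- data[data[[year_col]] == as.numeric(p), , drop = FALSE]
    if (nrow(sub) == 0L) stop(sprintf("no rows in period %s", p))
    out[[p]] <- tryCatch({
      fit <- fit_did(sub, outcome, factors, fe = fe, ...)
      tab <- wagstaff_decompose(fit, sub, income = income)
      tab$period <- p
      tab
    }, error = function(e) structure(list(message = conditionMessage(e)),
                                     class = "did_inestimable"))
  }
  out
}

#' Oaxaca-type decomposition of a contribution's change
#'
#' Splits the change between two periods in a factor's contribution to
#' the outcome's concentration index into a part due to the factor's own
#' inequality changing and a part due to the elasticity changing.  The
#' default weighting pairs the lagged elasticity with the CI change and
#' the current-period CI with the elasticity change:
#' \deqn{\Delta(\eta_k CI_k) = \eta_{k,t-1}\,\Delta CI_k +
#'   CI_{k,t}\,\Delta \eta_k,}
#' an exact algebraic identity.  The symmetric alternative (current
#' elasticity with \eqn{\Delta CI}, lagged CI with \eqn{\Delta\eta})
#' sums to the same total and is available via `weighting`.
#'
#' @param prev,curr `decomp_table`s for periods \eqn{t-1} and \eqn{t}
#'   (from [per_period_tables()] or [decomposition_table()]).
#' @param factor Factor whose contribution change is decomposed.
#' @param weighting `"lagged_elasticity"` (default) or
#'   `"current_elasticity"`.
#' @return Object of class `oaxaca_result` with the period pair, the
#'   elasticities and factor CIs in both periods, `ci_change_part`,
#'   `elasticity_change_part` and `total_change`.
#' @examples
#' prev <- decomposition_table("healthy", 0.56, 0.1068,
#'   data.frame(factor = "urrbmi", elasticity = -0.0016, factor_ci = 0.0369))
#' curr <- decomposition_table("healthy", 0.56, 0.0760,
#'   data.frame(factor = "urrbmi", elasticity = 0.0039, factor_ci = 0.1369))
#' oaxaca_change(prev, curr, "urrbmi")
#' @export
oaxaca_change <- function(prev, curr, factor,
                          weighting = c("lagged_elasticity",
                                        "current_elasticity")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(prev, "decomp_table"), inherits(curr, "decomp_table"))
  ip <- match(factor, prev$rows$factor)
  ic <- match(factor, curr$rows$factor)
  if (is.na(ip) || is.na(ic)) {
    stop(sprintf("factor '%s' missing from one of the periods", factor))
  }
  eta_prev <- prev$rows$elasticity[ip]
  eta_curr <- curr$rows$elasticity[ic]
  ci_prev <- prev$rows$factor_ci[ip]
  ci_curr <- curr$rows$factor_ci[ic]
  d_ci <- ci_curr - ci_prev
  d_eta <- eta_curr - eta_prev
  if (weighting == "lagged_elasticity") {
    ci_part <- eta_prev * d_ci
    eta_part <- ci_curr * d_eta
  } else {
    ci_part <- eta_curr * d_ci
    eta_part <- ci_prev * d_eta
  }
  structure(
    list(period_pair = c(prev$period %||% NA, curr$period %||% NA),
         factor = factor, eta_prev = eta_prev, eta_curr = eta_curr,
         ci_prev = ci_prev, ci_curr = ci_curr,
         ci_change_part = ci_part, elasticity_change_part = eta_part,
         total_change = eta_curr * ci_curr - eta_prev * ci_prev,
         weighting = weighting),
    class = "oaxaca_result"
  )
}

#' Table of contribution changes across consecutive periods
#'
#' Applies [oaxaca_change()] to every consecutive pair of period tables
#' and to the first-versus-last pair.
#'
#' @param tables Named list of `decomp_table`s keyed by period (as
#'   returned by [per_period_tables()]); inestimable periods are
#'   skipped.
#' @param factor Factor of interest.
#' @param weighting See [oaxaca_change()].
#' @return Data frame with one row per period pair: total contribution
#'   change, CI-change part and elasticity-change part.
#' @export
oaxaca_table <- function(tables, factor, weighting = "lagged_elasticity") {
  ok <- vapply(tables, inherits, logical(1), "decomp_table")
  tables <- tables[ok]
  ks <- names(tables)
  if (length(ks) < 2L) stop("need at least two estimable periods")
  pairs <- cbind(ks[-length(ks)], ks[-1L])
  if (length(ks) > 2L) pairs <- rbind(pairs, c(ks[1L], ks[length(ks)]))
  out <- apply(pairs, 1L, function(pr) {
    oc <- oaxaca_change(tables[[pr[1]]], tables[[pr[2]]], factor,
                        weighting = weighting)
    data.frame(period = paste(pr, collapse = "-"),
               total_change = oc$total_change,
               ci_change_part = oc$ci_change_part,
               elasticity_change_part = oc$elasticity_change_part)
  })
  do.call(rbind, out)
}

#' @export
print.oaxaca_result <- function(x, ...) {
  cat(sprintf("Change in contribution of '%s': %.4f\n",
              x$factor, x$total_change))
  cat(sprintf("  CI change part        %+0.4f  (eta %s x dCI %+0.4f)\n",
              x$ci_change_part,
              if (x$weighting == "lagged_elasticity") "t-1" else "t",
              x$ci_curr - x$ci_prev))
  cat(sprintf("  elasticity change part %+0.4f  (CI %s x deta %+0.4f)\n",
              x$elasticity_change_part,
              if (x$weighting == "lagged_elasticity") "t" else "t-1",
              x$eta_curr - x$eta_prev))
  invisible(x)
}
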