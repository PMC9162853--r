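#' Between-group term of a population-share decomposition
#'
#' Given the total concentration index and per-group sizes and
#' within-group indices (each computed with its own internal income
#' ranking), the between-group component is the residual of
#' \deqn{CI(y|I) = \sum_g \frac{N_g}{N} CI_g(y|I) + CI_{between},}
#' i.e. the part of total inequality not accounted for by
#' population-share-weighted intragroup inequality.
#'
#' @param total_ci Concentration index on the pooled sample.
#' @param n Vector of group sizes.
#' @param within_ci Vector of within-group concentration indices.
#' @return The between-group component.
#' @examples
#' between_group_ci(0.0963, c(3759, 30375), c(0.0866, 0.0946))
#' @export
between_group_ci <- function(total_ci, n, within_ci) {
  stopifnot(length(n) == length(within_ci), all(n > 0))
  total_ci - sum((n / sum(n)) * within_ci)
}

#' Between/within group decomposition of a concentration index
#'
#' Splits total income-related inequality in an outcome into
#' population-share-weighted intragroup inequality (each group ranked by
#' its own income distribution) plus a between-group residual, for a
#' binary or categorical partition such as urban/rural residence or
#' east/non-east region.  If a regression specification is supplied, a
#' full Wagstaff decomposition is additionally run inside each group to
#' report the focal (policy) factor's within-group concentration index
#' and contribution rate.
#'
#' @param data Data frame.
#' @param outcome Outcome column.
#' @param income Ranking column.
#' @param group Partition column (>= 2 nonempty levels).
#' @param factors Optional regressor set for the per-group
#'   decompositions; the first element is the focal policy factor.
#' @param fe Fixed effects for the per-group fits (see [fit_did()]).
#' @param se_type Passed to [fit_did()].
#' @return Object of class `group_decomp`: `partition`, `total_ci`,
#'   `focal` and a data frame `groups` with label, n, population share,
#'   within-group CI, and (when `factors` is given) the focal factor's
#'   within-group CI and contribution rate; plus `between_ci`,
#'   `between_focal_ci` and `between_rate` for the between row.  Groups
#'   whose outcome mean is zero are flagged with `NA` entries.
#' @export
decompose_by_group <- function(data, outcome, income, group,
                               factors = NULL, fe = c("city_id", "year"),
                               se_type = "robust") {
  stopifnot(is.data.frame(data))
  assert_columns(data, c(outcome, income, group))
  rows_ok <- which(stats::complete.cases(data[c(outcome, income, group)]))
  d <- data[rows_ok, , drop = FALSE]
  levels_g <- sort(unique(d[[group]]))
  if (length(levels_g) < 2L) stop("'group' must have at least 2 levels")

  total_ci <- concentration_index(d[[outcome]], d[[income]],
                                  outcome_name = outcome)$value
  focal <- if (!is.null(factors)) factors[1L] else NA_character_
  focal_total_ci <- if (!is.null(factors)) {
    concentration_index(d[[focal]], d[[income]])$value
  } else NA_real_
  total_rate <- NA_real_
  total_contribution <- NA_real_

  g_rows <- lapply(levels_g, function(g) {
    sub <- d[d[[group]] == g, , drop = FALSE]
    n_g <- nrow(sub)
    within <- tryCatch(
      concentration_index(sub[[outcome]], sub[[income]])$value,
      error = function(e) NA_real_)
    focal_ci <- contribution <- rate <- NA_real_
    if (!is.null(factors) && !is.na(within)) {
      focal_ci <- tryCatch(
        concentration_index(sub[[focal]], sub[[income]])$value,
        error = function(e) NA_real_)
      dec <- tryCatch({
        fit <- suppressWarnings(
          fit_did(sub, outcome, factors, fe = fe, se_type = se_type))
        wagstaff_decompose(fit, sub, income = income)
      }, error = function(e) NULL)
      if (!is.null(dec)) {
        i <- match(focal, dec$rows$factor)
        contribution <- dec$rows$contribution[i]
        rate <- dec$rows$contribution_rate[i]
      }
    }
    data.frame(group = as.character(g), n = n_g, share = n_g / nrow(d),
               within_ci = within, focal_ci = focal_ci,
               contribution = contribution, contribution_rate = rate)
  })
  groups <- do.call(rbind, g_rows)

  between_ci <- between_group_ci(total_ci, groups$n, groups$within_ci)
  between_focal <- if (!is.null(factors) && !anyNA(groups$focal_ci)) {
    between_group_ci(focal_total_ci, groups$n, groups$focal_ci)
  } else NA_real_

  between_contribution <- between_rate <- NA_real_
  if (!is.null(factors)) {
    dec_all <- tryCatch({
      fit <- suppressWarnings(
        fit_did(d, outcome, factors, fe = fe, se_type = se_type))
      wagstaff_decompose(fit, d, income = income)
    }, error = function(e) NULL)
    if (!is.null(dec_all) && !anyNA(groups$contribution)) {
      i <- match(focal, dec_all$rows$factor)
      total_contribution <- dec_all$rows$contribution[i]
      total_rate <- dec_all$rows$contribution_rate[i]
      between_contribution <- total_contribution -
        sum(groups$share * groups$contribution)
      between_rate <- 100 * between_contribution / total_ci
    }
  }

  structure(
    list(partition = group, outcome_name = outcome, total_ci = total_ci,
         focal = focal, focal_total_ci = focal_total_ci,
         total_contribution = total_contribution, total_rate = total_rate,
         groups = groups, between_ci = between_ci,
         between_focal_ci = between_focal,
         between_contribution = between_contribution,
         between_rate = between_rate, n = nrow(d)),
    class = "group_decomp"
  )
}

#' @export
print.group_decomp <- function(x, ...) {
  cat(sprintf("Group decomposition of CI(%s) = %.4f by '%s' (n = %d)\n",
              x$outcome_name, x$total_ci, x$partition, x$n))
  tab <- x$groups
  tab[-1] <- lapply(tab[-1], function(v) round(v, 4))
  print(tab, row.names = FALSE)
  cat(sprintf("Between-group: CI = %.4f", x$between_ci))
  if (!is.na(x$between_focal_ci)) {
    cat(sprintf(", focal CI = %.4f, rate = %.2f%%",
                x$between_focal_ci, x$between_rate))
  }
  cat("\n")
  invisible(x)
}
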