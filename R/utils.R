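# Internal numeric helpers shared across modules.

# Population covariance (divisor n), optionally weighted with weights
# normalised to sum to one.  The concentration index and the Wagstaff
# identity require the divisor-n convention on both sides; see the
# methods vignette.
pop_cov <- function(x, y, w = NULL) {
  if (is.null(w)) {
    mean(x * y) - mean(x) * mean(y)
  } else {
    w <- w / sum(w)
    sum(w * x * y) - sum(w * x) * sum(w * y)
  }
}

wtd_mean <- function(x, w = NULL) {
  if (is.null(w)) mean(x) else sum(w * x) / sum(w)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_columns <- function(data, cols, what = "column") {
  miss <- setdiff(cols, names(data))
  if (length(miss) > 0L) {
    stop(sprintf("unknown %s%s: %s", what, if (length(miss) > 1L) "s" else "",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

signif_stars <- function(p) {
  ifelse(p < 0.01, "***", ifelse(p < 0.05, "**", ifelse(p < 0.1, "*", "")))
}
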