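## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ratio of the 95th to the 5th percentile
#'
#' Percentiles are computed by linear interpolation between order statistics
#' (`stats::quantile` type 7). The ratio is undefined (`NA`) when the 5th
#' percentile is zero or negative, which downstream filters treat as a fail.
#'
#' @param x Numeric vector of expression values.
#' @param lower,upper Probabilities of the two percentiles (defaults 0.05 and
#'   0.95).
#' @return A single number, or `NA_real_` when undefined.
#' @export
percentile_ratio <- function(x, lower = 0.05, upper = 0.95) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  q <- stats::quantile(x, c(lower, upper), names = FALSE, type = 7)
  if (q[1] <= 0) return(NA_real_)
  q[2] / q[1]
}

#' Round a percentage to one decimal, half away from zero
#'
#' Reporting convention for all percentages in run summaries: one decimal
#' place, ties rounded away from zero (so 4.8737... prints as 4.9).
#'
#' @param x Numeric vector.
#' @return `x` rounded to one decimal.
#' @export
round_half_away <- function(x) {
  sign(x) * floor(abs(x) * 10 + 0.5) / 10
}

#' Percentage of a count over a total, reporting-rounded
#'
#' @param k Count of interest.
#' @param n Total count; must be positive.
#' @return `100 * k / n` rounded to one decimal, half away from zero.
#' @examples
#' prevalence_percent(6874, 141043)  # 4.9
#' prevalence_percent(1106, 8314)   # 13.3
#' @export
prevalence_percent <- function(k, n) {
  stopifnot(is.numeric(k), is.numeric(n), all(n > 0))
  round_half_away(100 * k / n)
}

## stopifnot-style check with a formatted message
check_that <- function(ok, ...) {
  if (!isTRUE(ok)) stop(sprintf(...), call. = FALSE)
  invisible(TRUE)
}
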