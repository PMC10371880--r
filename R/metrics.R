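#' Stability index of a trend
#'
#' Standard deviation (sample, n-1 denominator) of the first differences
#' of consecutive valid trend values -- a measure of short-term
#' variability; lower means more stable. Differences are taken between
#' consecutive valid samples even across short gaps, but pairs spanning
#' more than `max_gap` are excluded so missingness is not conflated with
#' instability.
#'
#' @param trend a [sampled_series()] (CPPopt trend, mmHg).
#' @param max_gap maximum time between paired samples in seconds (default
#'   600).
#' @return scalar mmHg, or `NA` when fewer than 3 valid samples (or fewer
#'   than 2 usable difference pairs) are available.
#' @export
stability_index <- function(trend, max_gap = 600) {
  stopifnot(inherits(trend, "sampled_series"))
  iv <- which(trend$valid)
  if (length(iv) < 3L) return(NA_real_)
  d <- diff(trend$values[iv])
  gap_ok <- diff(iv) * trend$dt <= max_gap
  d <- d[gap_ok]
  if (length(d) < 2L) return(NA_real_)
  stats::sd(d)
}

#' Yield of a CPPopt trend
#'
#' Percentage of CPP-monitored time for which a CPPopt value is
#' available: valid trend samples coincident with valid CPP samples, over
#' valid CPP samples.
#'
#' @param trend CPPopt [sampled_series()].
#' @param cpp CPP [sampled_series()] on the same grid.
#' @return percent in `[0, 100]`, or `NA` when CPP has no valid sample.
#' @export
yield_pct <- function(trend, cpp) {
  stopifnot(inherits(trend, "sampled_series"), inherits(cpp, "sampled_series"))
  if (trend$dt != cpp$dt || length(trend) != length(cpp))
    stop("trend and cpp must share cadence and length", call. = FALSE)
  denom <- sum(cpp$valid)
  if (denom == 0L) return(NA_real_)
  100 * sum(trend$valid & cpp$valid) / denom
}

#' Mean deviation of CPP from CPPopt
#'
#' Time-averaged signed difference CPP - CPPopt over pairwise-valid
#' ticks. Negative values mean CPP ran below the estimated optimum (the
#' direction associated with mortality), positive above it.
#'
#' @param cpp CPP [sampled_series()].
#' @param trend CPPopt [sampled_series()] on the same grid.
#' @return mmHg, or `NA` with no pairwise-valid overlap.
#' @export
delta_cppopt <- function(cpp, trend) {
  stopifnot(inherits(trend, "sampled_series"), inherits(cpp, "sampled_series"))
  if (trend$dt != cpp$dt || length(trend) != length(cpp))
    stop("trend and cpp must share cadence and length", call. = FALSE)
  i <- which(cpp$valid & trend$valid)
  if (!length(i)) return(NA_real_)
  mean(cpp$values[i] - trend$values[i])
}

#' Count abrupt jumps in a trend
#'
#' An abrupt jump is a change of more than `threshold` mmHg within less
#' than `horizon` seconds. A tick is flagged when any valid sample in its
#' trailing `(t - horizon, t)` differs from the tick's value by more than
#' the threshold; consecutive flagged ticks of one excursion collapse to
#' a single event (an event ends when the difference drops back to or
#' below the threshold).
#'
#' @param trend a [sampled_series()].
#' @param threshold jump size in mmHg (default 10).
#' @param horizon look-back in seconds (default 300).
#' @return integer event count.
#' @export
count_jumps <- function(trend, threshold = 10, horizon = 300) {
  stopifnot(inherits(trend, "sampled_series"))
  if (trend$dt > horizon)
    stop("cadence must not exceed the horizon", call. = FALSE)
  k <- as.integer(floor(horizon / trend$dt))
  iv <- which(trend$valid)
  x <- trend$values
  flagged <- logical(length(iv))
  for (q in seq_along(iv)) {
    i <- iv[q]
    back <- iv[iv >= i - k + 1L & iv < i]   # strictly earlier, within horizon
    if (length(back))
      flagged[q] <- any(abs(x[i] - x[back]) > threshold)
  }
  sum(flagged & !c(FALSE, flagged[-length(flagged)]))
}

#' Fraction of plausible trend values
#'
#' Fraction of valid samples strictly inside the physiologically
#' plausible band `(lo, hi)` -- by default > 50 and < 100 mmHg.
#'
#' @param trend a [sampled_series()].
#' @param lo,hi exclusive band limits in mmHg.
#' @return fraction in `[0, 1]`, or `NA` with no valid sample.
#' @export
plausible_frac <- function(trend, lo = 50, hi = 100) {
  stopifnot(inherits(trend, "sampled_series"))
  v <- trend$values[trend$valid]
  if (!length(v)) return(NA_real_)
  mean(v > lo & v < hi)
}

#' Quality report for one CPPopt trend
#'
#' Bundles the trend-quality metrics used to judge algorithm variants:
#' stability index, yield, mean deviation of CPP from CPPopt, abrupt-jump
#' count, plausible-value fraction and time of the first available value.
#'
#' @param trend smoothed CPPopt [sampled_series()] (or a `cppopt_trend`,
#'   from which `smoothed` and `cpp` are taken).
#' @param cpp CPP [sampled_series()] on the same grid (ignored when
#'   `trend` is a `cppopt_trend`).
#' @return A `trend_report` list: `stability_index` (mmHg), `yield_pct`,
#'   `delta_cppopt` (mmHg), `n_jumps`, `plausible_frac`,
#'   `first_value_time` (seconds from series start, `NA` if never).
#' @export
trend_report <- function(trend, cpp = NULL) {
  offset <- 0
  if (inherits(trend, "cppopt_trend")) {
    cpp <- trend$cpp
    trend <- trend$smoothed
    offset <- trend$dt          # minute ticks start one cadence after t0
  }
  stopifnot(inherits(trend, "sampled_series"), inherits(cpp, "sampled_series"))
  iv <- which(trend$valid)
  structure(
    list(
      stability_index = stability_index(trend),
      yield_pct = yield_pct(trend, cpp),
      delta_cppopt = delta_cppopt(cpp, trend),
      n_jumps = count_jumps(trend),
      plausible_frac = plausible_frac(trend),
      first_value_time = if (length(iv))
        (iv[1] - 1L) * trend$dt + offset else NA_real_
    ),
    class = "trend_report"
  )
}

#' @export
print.trend_report <- function(x, ...) {
  cat("<trend_report>\n")
  cat(sprintf("  stability index : %s mmHg\n", fmt_num(x$stability_index)))
  cat(sprintf("  yield           : %s %%\n", fmt_num(x$yield_pct)))
  cat(sprintf("  delta CPP-CPPopt: %s mmHg\n", fmt_num(x$delta_cppopt)))
  cat(sprintf("  jumps (>10 mmHg): %d\n", x$n_jumps))
  cat(sprintf("  plausible frac  : %s\n", fmt_num(x$plausible_frac)))
  cat(sprintf("  first value at  : %s h\n",
              fmt_num(x$first_value_time / 3600)))
  invisible(x)
}

fmt_num <- function(x) if (is.na(x)) "NA" else sprintf("%.3g", x)
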