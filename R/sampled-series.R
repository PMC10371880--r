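#' Gap-aware uniformly sampled time series
#'
#' A `sampled_series` stores a uniformly sampled scalar signal (mmHg for
#' ABP/ICP/CPP, dimensionless for PRx) together with a parallel logical
#' validity mask. Timestamps are implicit: sample `i` (1-based) sits at
#' `start_time + (i - 1) * dt`. Invalid samples carry no information; no
#' operation in this package ever reads the stored value of an invalid
#' sample, so callers may leave arbitrary garbage there.
#'
#' @param values numeric vector of sample values.
#' @param dt sampling interval in seconds (positive scalar).
#' @param start_time `POSIXct` timestamp of the first sample.
#' @param valid logical vector, same length as `values`; defaults to
#'   `!is.na(values)`.
#'
#' @return An object of class `sampled_series`: a list with fields
#'   `values`, `valid`, `dt`, `start_time`.
#' @examples
#' s <- sampled_series(c(80, 82, NA, 85), dt = 10)
#' s$valid
#' @export
sampled_series <- function(values, dt,
                           start_time = as.POSIXct("1970-01-01", tz = "UTC"),
                           valid = !is.na(values)) {
  values <- as.numeric(values)
  valid <- as.logical(valid)
  if (length(valid) != length(values))
    stop("`values` and `valid` must have identical length", call. = FALSE)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("`dt` must be a positive scalar (seconds)", call. = FALSE)
  if (!inherits(start_time, "POSIXct"))
    start_time <- as.POSIXct(start_time, tz = "UTC")
  valid[is.na(valid)] <- FALSE
  valid <- valid & !is.na(values) & is.finite(ifelse(valid, values, 0))
  structure(
    list(values = values, valid = valid, dt = as.numeric(dt),
         start_time = start_time),
    class = "sampled_series"
  )
}

#' @export
length.sampled_series <- function(x) length(x$values)

#' Sample timestamps of a series
#'
#' @param x a [sampled_series()].
#' @return `POSIXct` vector of per-sample timestamps.
#' @export
series_times <- function(x) {
  stopifnot(inherits(x, "sampled_series"))
  x$start_time + (seq_along(x$values) - 1) * x$dt
}

#' @export
print.sampled_series <- function(x, ...) {
  n <- length(x$values)
  cat(sprintf("<sampled_series> %d samples @ %gs, %d valid (%.1f%%)\n",
              n, x$dt, sum(x$valid), if (n) 100 * mean(x$valid) else 0))
  cat(sprintf("  start: %s  span: %.2f h\n",
              format(x$start_time, "%Y-%m-%d %H:%M:%S"), n * x$dt / 3600))
  invisible(x)
}

#' @export
as.data.frame.sampled_series <- function(x, row.names = NULL, optional = FALSE,
                                         ...) {
  data.frame(datetime = series_times(x),
             value = ifelse(x$valid, x$values, NA_real_))
}

# values with invalid samples replaced by NA -- the only sanctioned way to
# look at the payload, so poisoned invalid entries can never leak.
masked_values <- function(x) {
  v <- x$values
  v[!x$valid] <- NA_real_
  v
}

#' Block-average a series to a coarser cadence
#'
#' Averages consecutive non-overlapping blocks of `target_dt / dt` samples
#' (e.g. waveform-rate pressures down to the 10-s averages PRx consumes).
#' A block's output is the mean of its valid samples, and is invalid when
#' fewer than `min_fraction` of the block's samples are valid. A trailing
#' partial block is dropped.
#'
#' @param series a [sampled_series()].
#' @param target_dt output sampling interval in seconds; must be an integer
#'   multiple of `series$dt`.
#' @param min_fraction minimum fraction (0, 1] of valid samples a block
#'   needs for its average to be emitted. Default 0.5, mirroring the 50%
#'   missing-data convention used throughout the CPPopt pipeline.
#' @return A [sampled_series()] at cadence `target_dt`.
#' @examples
#' s <- sampled_series(c(1, 2, 3, 4, 5, 6), dt = 1)
#' block_average(s, 3)$values
#' @export
block_average <- function(series, target_dt, min_fraction = 0.5) {
  stopifnot(inherits(series, "sampled_series"))
  ratio <- target_dt / series$dt
  if (abs(ratio - round(ratio)) > 1e-9 || ratio < 1)
    stop(sprintf("target_dt (%g s) is not an integer multiple of dt (%g s)",
                 target_dt, series$dt), call. = FALSE)
  if (!(min_fraction > 0 && min_fraction <= 1))
    stop("`min_fraction` must be in (0, 1]", call. = FALSE)
  k <- as.integer(round(ratio))
  n_out <- length(series$values) %/% k
  if (n_out == 0L)
    return(sampled_series(numeric(0), target_dt, series$start_time))
  idx <- seq_len(n_out * k)
  grp <- rep(seq_len(n_out), each = k)
  v <- series$valid[idx]
  x <- series$values[idx]
  x[!v] <- 0
  cnt <- as.numeric(tapply(v, grp, sum))
  sm <- as.numeric(tapply(x, grp, sum))
  ok <- cnt >= min_fraction * k & cnt > 0
  out <- ifelse(ok, sm / cnt, NA_real_)
  sampled_series(out, target_dt, series$start_time, valid = ok)
}

#' Trailing moving mean / median filter
#'
#' Causal (trailing) moving-window filter: the output at time `t` is the
#' chosen statistic over the valid samples in `(t - window, t]`. Trailing
#' alignment is deliberate -- the CPPopt pipeline is designed for
#' prospective bedside use, so no filter may look into the future. The
#' output sample is invalid when its window holds no valid sample. With an
#' even count of valid samples, the median is the midpoint of the two
#' central values (the `stats::median` convention).
#'
#' @param series a [sampled_series()].
#' @param window window length in seconds; integer multiple of `series$dt`.
#' @param statistic `"mean"` or `"median"`.
#' @param alignment only `"trailing"` is supported.
#' @return A [sampled_series()] on the same grid as the input.
#' @export
moving_filter <- function(series, window, statistic = c("mean", "median"),
                          alignment = "trailing") {
  stopifnot(inherits(series, "sampled_series"))
  statistic <- match.arg(statistic)
  if (!identical(alignment, "trailing"))
    stop("only trailing (causal) alignment is supported", call. = FALSE)
  ratio <- window / series$dt
  if (abs(ratio - round(ratio)) > 1e-9 || ratio < 1)
    stop(sprintf("window (%g s) is not an integer multiple of dt (%g s)",
                 window, series$dt), call. = FALSE)
  k <- as.integer(round(ratio))
  n <- length(series$values)
  out <- trailing_stat_at(series, k, statistic, seq_len(n))
  sampled_series(out, series$dt, series$start_time, valid = !is.na(out))
}

# Statistic over the trailing k-sample window ending at each index in `at`
# (1-based). NA where the window holds no valid sample. Shared between
# moving_filter (all indices) and the engine (minute ticks only).
trailing_stat_at <- function(series, k, statistic, at) {
  v <- series$valid
  x <- series$values
  if (statistic == "mean") {
    xv <- ifelse(v, x, 0)
    cs <- cumsum(xv)
    cv <- cumsum(as.numeric(v))
    lo <- pmax(at - k, 0L)
    sm <- cs[at] - c(0, cs)[lo + 1L]
    cnt <- cv[at] - c(0, cv)[lo + 1L]
    return(ifelse(cnt > 0, sm / cnt, NA_real_))
  }
  vapply(at, function(i) {
    j <- max(1L, i - k + 1L):i
    w <- x[j][v[j]]
    if (length(w) == 0L) NA_real_ else stats::median(w)
  }, numeric(1))
}
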