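#' Fisher transform of a correlation coefficient
#'
#' `arctanh` applied after clipping to `[-1 + clip_eps, 1 - clip_eps]`, so
#' boundary correlations map to large finite values instead of infinities.
#' Used to unbound and approximately normalize PRx before binning and
#' curve fitting; odd and strictly increasing on its domain.
#'
#' @param prx numeric vector of correlations in `[-1, 1]` (values outside
#'   are clipped too).
#' @param clip_eps clipping margin (default `1e-6`).
#' @return numeric vector, `atanh` of the clipped input.
#' @examples
#' fisher_transform(c(-1, 0, 0.5, 1))
#' @export
fisher_transform <- function(prx, clip_eps = 1e-6) {
  stopifnot(is.numeric(clip_eps), clip_eps > 0, clip_eps < 1)
  atanh(pmin(pmax(prx, -1 + clip_eps), 1 - clip_eps))
}

#' Pressure-reactivity index from 10-s averaged ABP and ICP
#'
#' PRx is the moving Pearson correlation between 10-s averages of arterial
#' blood pressure and intracranial pressure over a trailing 5-min window,
#' emitted every minute. A near-zero or negative PRx indicates intact
#' cerebrovascular pressure reactivity; positive values indicate
#' impairment. The minute series is Fisher-transformed
#' ([fisher_transform()]) into `prx_ft` for downstream curve fitting.
#'
#' Output ticks sit at `start_time + cadence * (1, 2, ...)`; the tick at
#' time `t` correlates the pairwise-valid samples in `(t - window, t]`. A
#' tick is invalid when fewer than `min_pairs` valid pairs are available
#' or when either signal is constant over the window (the correlation is
#' undefined there; emitting 0 instead would silently bias the PRx-CPP
#' curve fit).
#'
#' @param abp10,icp10 aligned [sampled_series()] (same `start_time`, `dt`,
#'   length), conventionally at 10-s cadence.
#' @param window correlation window in seconds (default 300).
#' @param cadence emission cadence in seconds (default 60); integer
#'   multiple of the input `dt`.
#' @param min_pairs minimum pairwise-valid sample count per window
#'   (default 15 = 50% of the 30 pairs a 5-min window holds at 10 s).
#' @return A list of class `prx_series`: `prx` and `prx_ft` as
#'   [sampled_series()] at `cadence`, plus `window` and `cadence`.
#' @export
compute_prx <- function(abp10, icp10, window = 300, cadence = 60,
                        min_pairs = 15) {
  stopifnot(inherits(abp10, "sampled_series"), inherits(icp10, "sampled_series"))
  if (abp10$dt != icp10$dt || length(abp10) != length(icp10) ||
      abs(as.numeric(difftime(abp10$start_time, icp10$start_time,
                              units = "secs"))) > 1e-6)
    stop("ABP and ICP series are not aligned (start_time/dt/length differ)",
         call. = FALSE)
  dt <- abp10$dt
  for (nm in c(window = window, cadence = cadence)) {
    if (abs(nm / dt - round(nm / dt)) > 1e-9)
      stop("window and cadence must be integer multiples of dt", call. = FALSE)
  }
  kw <- as.integer(round(window / dt))
  kc <- as.integer(round(cadence / dt))
  n <- length(abp10)
  n_ticks <- (n - 1L) %/% kc
  prx <- rep(NA_real_, n_ticks)
  pv <- abp10$valid & icp10$valid
  a <- abp10$values
  b <- icp10$values
  for (m in seq_len(n_ticks)) {
    i1 <- m * kc + 1L                    # 1-based index of sample at tick time
    i0 <- max(1L, i1 - kw + 1L)
    j <- i0:i1
    j <- j[pv[j]]
    if (length(j) < min_pairs) next
    aw <- a[j]; bw <- b[j]
    if (stats::sd(aw) == 0 || stats::sd(bw) == 0) next
    prx[m] <- stats::cor(aw, bw)
  }
  t1 <- abp10$start_time + cadence
  structure(
    list(prx = sampled_series(prx, cadence, t1),
         prx_ft = sampled_series(fisher_transform(prx), cadence, t1),
         window = window, cadence = cadence),
    class = "prx_series"
  )
}

#' @export
print.prx_series <- function(x, ...) {
  cat(sprintf("<prx_series> window %gs, cadence %gs\n", x$window, x$cadence))
  print(x$prx)
  invisible(x)
}
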