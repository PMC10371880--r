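# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. seed = NULL runs on the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(expr)
}

#' Fourier phase-randomized surrogate of a series
#'
#' Builds a pure-noise surrogate: the signal is Fourier transformed, the
#' phases of all non-DC, non-Nyquist components are replaced by i.i.d.
#' uniform draws (conjugate-symmetrically, so the output is real), and the
#' transform inverted. The amplitude spectrum -- hence mean, variance and
#' the full autocorrelation / dynamic range -- is preserved exactly, but
#' any phase-locked relationship with another signal is destroyed. Feeding
#' independently phase-randomized ABP and ICP surrogates to the CPPopt
#' engine probes its false-positive behaviour: ideally no CPPopt should be
#' produced from such noise.
#'
#' @param series a gap-free [sampled_series()] (length >= 4); gapped input
#'   is an error -- interpolate or trim first.
#' @param seed integer seed for the phase draws (`NULL` = current RNG).
#' @return A [sampled_series()] of identical length, cadence and amplitude
#'   spectrum.
#' @export
phase_randomize <- function(series, seed = NULL) {
  stopifnot(inherits(series, "sampled_series"))
  if (!all(series$valid))
    stop("phase_randomize requires a gap-free series (all samples valid)",
         call. = FALSE)
  n <- length(series)
  if (n < 4L) stop("series too short to phase-randomize (need >= 4 samples)",
                   call. = FALSE)
  x <- series$values
  F <- stats::fft(x)
  half <- (n - 1L) %/% 2L                 # indices 2..half+1 are free phases
  phases <- with_seed(seed, stats::runif(half, 0, 2 * pi))
  Fnew <- F
  if (half > 0L) {
    k <- 2L:(half + 1L)
    Fnew[k] <- Mod(F[k]) * exp(1i * phases)
    Fnew[n + 2L - k] <- Conj(Fnew[k])
  }
  # DC (and Nyquist, for even n) stay untouched: they must remain real
  out <- Re(stats::fft(Fnew, inverse = TRUE)) / n
  sampled_series(out, series$dt, series$start_time)
}

#' Specification of a simulated virtual patient
#'
#' Describes a ground-truth world for parameter-recovery testing: a
#' programmable U-shaped autoregulation curve `rho(CPP)` (the target
#' ABP-ICP correlation, i.e. the PRx the estimator should recover) with a
#' known optimum, a slow bounded random-walk CPP trajectory, noise levels
#' and an optional gap schedule.
#'
#' By default `rho(CPP) = curvature * (CPP - true_opt)^2 + rho_min`,
#' clipped to `[-0.99, 0.99]`: reactivity is best (most negative PRx) at
#' `true_opt` and deteriorates quadratically away from it. The defaults
#' (`rho_min = -0.3`, `curvature = 0.004`) put `rho` at `-0.3` at the
#' optimum and `+0.6` 15 mmHg away -- spanning the PRx band the engine's
#' acceptance criteria regard as informative.
#'
#' @param duration recording length in seconds (default 10 h).
#' @param true_opt ground-truth optimal CPP in mmHg.
#' @param prx_curve optional numeric `c(a, b, c)` mapping CPP to target
#'   correlation; overrides `rho_min`/`curvature`.
#' @param rho_min correlation at the optimum (default -0.3).
#' @param curvature quadratic coefficient of the U-shape (default 0.004
#'   per mmHg^2).
#' @param cpp_mean,cpp_drift_sd,cpp_min,cpp_max bounded random-walk CPP
#'   trajectory: start/centre (mmHg), per-5-min drift SD (mmHg), and
#'   reflecting bounds.
#' @param icp_baseline mean ICP in mmHg (default 10).
#' @param abp_sd,icp_sd slow-wave fluctuation amplitudes in mmHg.
#' @param noise_sd additional independent sensor noise SD in mmHg added to
#'   both signals after the correlation linkage (default 0.5).
#' @param gap_schedule list of `c(start, length)` pairs in seconds marking
#'   invalid intervals, applied after synthesis (ground truth stays
#'   defined inside gaps).
#' @param seed integer RNG seed.
#' @return A `virtual_patient_spec` list.
#' @export
virtual_patient_spec <- function(duration = 36000, true_opt = 75,
                                 prx_curve = NULL, rho_min = -0.3,
                                 curvature = 0.004, cpp_mean = true_opt,
                                 cpp_drift_sd = 3, cpp_min = 60, cpp_max = 90,
                                 icp_baseline = 10, abp_sd = 5, icp_sd = 2,
                                 noise_sd = 0.5, gap_schedule = list(),
                                 seed = 1L) {
  if (is.null(prx_curve)) {
    a <- curvature
    prx_curve <- c(a = a, b = -2 * a * true_opt,
                   c = a * true_opt^2 + rho_min)
  }
  if (cpp_min < 0 || cpp_max > 150 || cpp_min >= cpp_max)
    stop("CPP bounds must satisfy 0 <= cpp_min < cpp_max <= 150 mmHg",
         call. = FALSE)
  if (prx_curve[1] <= 0 || true_opt < cpp_min || true_opt > cpp_max)
    stop("rho(true_opt) must be the minimum of prx_curve over the CPP bounds",
         call. = FALSE)
  structure(
    list(duration = duration, true_opt = true_opt, prx_curve = prx_curve,
         cpp_mean = cpp_mean, cpp_drift_sd = cpp_drift_sd,
         cpp_min = cpp_min, cpp_max = cpp_max, icp_baseline = icp_baseline,
         abp_sd = abp_sd, icp_sd = icp_sd, noise_sd = noise_sd,
         gap_schedule = gap_schedule, seed = as.integer(seed)),
    class = "virtual_patient_spec"
  )
}

# target correlation at a given CPP, clipped to a fittable range
rho_at <- function(spec, cpp) {
  r <- spec$prx_curve[1] * cpp^2 + spec$prx_curve[2] * cpp + spec$prx_curve[3]
  pmin(pmax(r, -0.99), 0.99)
}

#' Simulate a virtual patient's 10-s ABP and ICP series
#'
#' Generates minute-scale slow-wave dynamics in 5-min blocks: within each
#' block the CPP level follows a bounded random walk, a standardized ABP
#' slow-wave fluctuation is drawn (smoothed AR(1) noise), and the
#' standardized ICP fluctuation is constructed as
#' `rho * z_abp + sqrt(1 - rho^2) * z_noise` with `z_noise` orthogonalized
#' against `z_abp` within the block -- so the in-block sample correlation
#' of the fluctuations (the quantity PRx estimates) equals `rho(CPP)`
#' exactly up to sensor noise. Gaps are applied last. Both outputs are
#' floored at 0 mmHg.
#'
#' @param spec a [virtual_patient_spec()].
#' @return list with `abp10` and `icp10` ([sampled_series()] at 10-s
#'   cadence) and `cpp_blocks` (the ground-truth block CPP levels).
#' @export
simulate_patient <- function(spec) {
  stopifnot(inherits(spec, "virtual_patient_spec"))
  dt <- 10
  block_len <- 30L                       # 5 min of 10-s samples
  n <- as.integer(floor(spec$duration / dt))
  n_blocks <- as.integer(ceiling(n / block_len))
  with_seed(spec$seed, {
    # bounded (reflecting) random walk of the CPP level, one step per block
    cpp_b <- numeric(n_blocks)
    cpp_b[1] <- spec$cpp_mean
    if (n_blocks > 1) {
      steps <- stats::rnorm(n_blocks - 1L, 0, spec$cpp_drift_sd)
      for (k in 2:n_blocks) {
        x <- cpp_b[k - 1] + steps[k - 1]
        if (x > spec$cpp_max) x <- 2 * spec$cpp_max - x
        if (x < spec$cpp_min) x <- 2 * spec$cpp_min - x
        cpp_b[k] <- min(max(x, spec$cpp_min), spec$cpp_max)
      }
    }
    abp <- numeric(n_blocks * block_len)
    icp <- numeric(n_blocks * block_len)
    for (k in seq_len(n_blocks)) {
      rho <- rho_at(spec, cpp_b[k])
      za <- standardize(smooth_noise(block_len))
      zn <- standardize(orthogonalize(smooth_noise(block_len), za))
      zi <- rho * za + sqrt(1 - rho^2) * zn
      i <- (k - 1L) * block_len + seq_len(block_len)
      icp[i] <- spec$icp_baseline + spec$icp_sd * zi
      abp[i] <- cpp_b[k] + spec$icp_baseline + spec$abp_sd * za
    }
    abp <- abp[seq_len(n)]
    icp <- icp[seq_len(n)]
    if (spec$noise_sd > 0) {
      abp <- abp + stats::rnorm(n, 0, spec$noise_sd)
      icp <- icp + stats::rnorm(n, 0, spec$noise_sd)
    }
    abp <- pmax(abp, 0)
    icp <- pmax(icp, 0)
    valid <- rep(TRUE, n)
    for (g in spec$gap_schedule) {
      i0 <- max(1L, as.integer(floor(g[1] / dt)) + 1L)
      i1 <- min(n, as.integer(ceiling((g[1] + g[2]) / dt)))
      if (i0 <= i1) valid[i0:i1] <- FALSE
    }
    t0 <- as.POSIXct("2026-01-01", tz = "UTC")
    list(abp10 = sampled_series(abp, dt, t0, valid = valid),
         icp10 = sampled_series(icp, dt, t0, valid = valid),
         cpp_blocks = cpp_b)
  })
}

# AR(1)-smoothed standard normal noise: minute-scale slow waves at 10 s
smooth_noise <- function(n, phi = 0.8) {
  as.numeric(stats::filter(stats::rnorm(n), phi, method = "recursive"))
}

standardize <- function(x) {
  s <- stats::sd(x)
  if (s == 0) return(x * 0)
  (x - mean(x)) / s
}

orthogonalize <- function(x, against) {
  den <- sum(against^2)
  if (den == 0) return(x)
  x - against * sum(x * against) / den
}
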