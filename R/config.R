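#' CPPopt engine configuration
#'
#' The full curve-fitting and weighting parameter set of the multi-window
#' weighted CPPopt algorithm. The two presets reproduce the fine-tuned
#' algorithm (`variant = "new"`, the default) and its predecessor
#' (`variant = "previous"`, often called CPPopt_MA); any field can be
#' overridden individually. The variants differ only in configuration --
#' both run through one code path:
#'
#' * `cpp_prefilter`: `"median"` (new) vs `"mean"` (previous), 5-min
#'   trailing window over the 10-s CPP samples.
#' * `min_bin_count_frac`: 0.03 (new) vs 0.02 (previous) -- a CPP bin must
#'   hold at least this fraction of the window's data to enter the fit.
#' * `r2_full_min`: 0.2 (new) vs `NA` = disabled (previous) -- minimum
#'   coefficient of determination evaluated over *all* non-empty bins,
#'   including those excluded from the fit.
#' * `weighting`: `"new"` (weight = R^2_full for accepted parabolic fits)
#'   vs `"previous"` (weight = exp(-hours) * exp(-RMSE) * W_nonparabolic).
#'
#' @param variant `"new"` or `"previous"` preset.
#' @param ... named overrides of any configuration field. Unknown names
#'   are an error.
#'
#' @section Fields:
#' \describe{
#'   \item{cpp_prefilter, cpp_prefilter_window}{statistic and trailing
#'     window (s) for CPP pre-processing; default median over 300 s.}
#'   \item{n_bins, bin_min, bin_max}{CPP binning: 16 half-open bins over
#'     40--120 mmHg, i.e. 5-mmHg bins.}
#'   \item{min_bin_count_frac}{minimum per-bin fraction of the window's
#'     valid data for the bin to be included in the fit.}
#'   \item{min_included_frac}{minimum fraction of the window's valid data
#'     that the included bins must jointly cover (0.5).}
#'   \item{min_y_span}{minimum span of the fitted curve over the included
#'     CPP range, in Fisher-transformed PRx units (0.2): flatter curves
#'     carry no optimum information and are rejected.}
#'   \item{y_region_min, y_region_max}{the PRx band (-0.3, 0.6) the fitted
#'     curve must overlap: uniformly very high PRx (reactivity lost at
#'     every CPP) or uniformly very low PRx (preserved everywhere) admits
#'     no optimum.}
#'   \item{r2_full_min}{minimum R^2 over all non-empty bins, or `NA` to
#'     disable the criterion.}
#'   \item{weighting}{`"new"` or `"previous"` weighting scheme.}
#'   \item{window_min, window_max, window_step, n_windows}{look-back
#'     window enumeration: 36 windows ending at 8 h in 10-min steps.}
#'   \item{ewa_alpha, ewa_window}{exponentially weighted average: weights
#'     `(1 - alpha)^k` with `alpha = 0.1` over a 2-h (7200 s) buffer.}
#'   \item{missing_data_limit}{maximum tolerated missing-data fraction in
#'     the calculation buffer (0.5); with an 8-h maximal window this makes
#'     4 h of continuously acquired data the warm-up requirement before
#'     the first CPPopt value.}
#'   \item{update_cadence}{CPPopt update interval in seconds (60).}
#'   \item{prx_window, prx_cadence, prx_min_pairs}{PRx estimator settings
#'     passed to [compute_prx()].}
#' }
#'
#' @return A named list of class `cppopt_config`.
#' @examples
#' cfg <- cppopt_config()                       # fine-tuned algorithm
#' ma  <- cppopt_config("previous")             # CPPopt_MA
#' cppopt_config(min_y_span = 0.3)$min_y_span
#' @export
cppopt_config <- function(variant = c("new", "previous"), ...) {
  variant <- match.arg(variant)
  cfg <- list(
    cpp_prefilter = "median",
    cpp_prefilter_window = 300,
    n_bins = 16L,
    bin_min = 40,
    bin_max = 120,
    min_bin_count_frac = 0.03,
    min_included_frac = 0.5,
    min_y_span = 0.2,
    y_region_min = -0.3,
    y_region_max = 0.6,
    r2_full_min = 0.2,
    weighting = "new",
    window_min = 7200,
    window_max = 28800,
    window_step = 600,
    n_windows = 36L,
    ewa_alpha = 0.1,
    ewa_window = 7200,
    missing_data_limit = 0.5,
    update_cadence = 60,
    prx_window = 300,
    prx_cadence = 60,
    prx_min_pairs = 15L
  )
  if (variant == "previous") {
    cfg$cpp_prefilter <- "mean"
    cfg$min_bin_count_frac <- 0.02
    cfg$r2_full_min <- NA_real_
    cfg$weighting <- "previous"
  }
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad) || is.null(names(dots)) || any(!nzchar(names(dots))))
      stop("unknown configuration field(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    cfg[names(dots)] <- dots
  }
  cfg$variant <- variant
  class(cfg) <- "cppopt_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  with(cfg, {
    if (!(bin_min < bin_max)) stop("bin_min must be < bin_max", call. = FALSE)
    if (n_bins < 1) stop("n_bins must be >= 1", call. = FALSE)
    if (!cpp_prefilter %in% c("mean", "median"))
      stop("cpp_prefilter must be 'mean' or 'median'", call. = FALSE)
    if (!weighting %in% c("new", "previous"))
      stop("weighting must be 'new' or 'previous'", call. = FALSE)
    if (!(ewa_alpha > 0 && ewa_alpha < 1))
      stop("ewa_alpha must be in (0, 1)", call. = FALSE)
    if (!(missing_data_limit > 0 && missing_data_limit <= 1))
      stop("missing_data_limit must be in (0, 1]", call. = FALSE)
    if (!is.na(r2_full_min) && (r2_full_min < 0 || r2_full_min > 1))
      stop("r2_full_min must be in [0, 1] or NA (disabled)", call. = FALSE)
  })
  enumerate_windows(cfg)   # validates the (min, max, step, n) quadruple
  invisible(cfg)
}

#' @export
print.cppopt_config <- function(x, ...) {
  cat(sprintf("<cppopt_config> variant '%s'\n", x$variant))
  cat(sprintf("  CPP prefilter: %s over %g s; bins: %d x %g mmHg in [%g, %g)\n",
              x$cpp_prefilter, x$cpp_prefilter_window, x$n_bins,
              (x$bin_max - x$bin_min) / x$n_bins, x$bin_min, x$bin_max))
  cat(sprintf("  windows: %d from %g to %g s (step %g); weighting: %s\n",
              x$n_windows, min(enumerate_windows(x)), x$window_max,
              x$window_step, x$weighting))
  cat(sprintf("  bin count >= %g%%, included >= %g%%, y-span >= %g, y-region [%g, %g], R2_full >= %s\n",
              100 * x$min_bin_count_frac, 100 * x$min_included_frac,
              x$min_y_span, x$y_region_min, x$y_region_max,
              if (is.na(x$r2_full_min)) "(disabled)" else x$r2_full_min))
  invisible(x)
}

#' Enumerate the look-back window lengths
#'
#' Returns the strictly increasing window lengths (seconds) the engine
#' fits at every update tick. The enumeration is anchored at the longest
#' window: lengths are `window_max - window_step * (n_windows-1, ..., 0)`,
#' which at defaults yields 36 windows from 2 h 10 min up to 8 h in 10-min
#' steps. (The naive "2 h to 8 h inclusive by 10 min" arithmetic gives 37;
#' the established count is 36, and anchoring the 8-h window keeps the
#' 4-h warm-up exact.)
#'
#' @param config a [cppopt_config()].
#' @return numeric vector of `n_windows` window lengths in seconds.
#' @examples
#' length(enumerate_windows(cppopt_config()))   # 36
#' @export
enumerate_windows <- function(config) {
  w <- with(config, window_max - window_step * ((n_windows - 1L):0L))
  degenerate <- config$n_windows == 1L && config$window_min == config$window_max
  if (!degenerate) {
    if (!(config$window_min < config$window_max))
      stop("window_min must be < window_max", call. = FALSE)
    if (abs((config$window_max - config$window_min) -
            config$window_step * config$n_windows) > 1e-9)
      stop(sprintf(
        paste0("inconsistent window quadruple: (window_max - window_min) / ",
               "window_step = (%g - %g) / %g = %g, but n_windows = %d ",
               "(enumeration runs from window_min + window_step to window_max)"),
        config$window_max, config$window_min, config$window_step,
        (config$window_max - config$window_min) / config$window_step,
        config$n_windows), call. = FALSE)
  }
  w
}

#' Read a CPPopt configuration from a JSON file
#'
#' Keys are the snake_cased field names of [cppopt_config()]; an optional
#' `"variant"` key selects the preset the remaining keys override.
#' Unknown keys are an error.
#'
#' @param path path to a JSON file.
#' @return A [cppopt_config()].
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  variant <- x$variant %||% "new"
  x$variant <- NULL
  do.call(cppopt_config, c(list(variant = variant), x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
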