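#' Bin paired CPP / Fisher-PRx samples for one look-back window
#'
#' Collects the pairwise-valid (CPP, Fisher-transformed PRx) samples in
#' the trailing window `(at - window_length, at]`, discards samples whose
#' CPP falls outside `[bin_min, bin_max)`, and groups the rest into
#' `n_bins` half-open 5-mmHg bins, recording per-bin counts and mean CPP /
#' mean PRx_ft. A bin is flagged `included` (available for curve fitting)
#' when it holds at least `min_bin_count_frac` of the window's valid data
#' count, so CPP values represented only by short spikes or drops are
#' disregarded.
#'
#' @param cpp pre-filtered CPP trend as a [sampled_series()] at the update
#'   cadence (60 s).
#' @param prx_ft Fisher-transformed PRx as a [sampled_series()] aligned
#'   with `cpp`.
#' @param window_length look-back duration in seconds.
#' @param at right edge of the window: a `POSIXct`, or seconds offset from
#'   `cpp$start_time`.
#' @param config a [cppopt_config()].
#' @return A `binned_curve`: list with `edges` (length `n_bins + 1`),
#'   `counts`, `mean_cpp`, `mean_prx_ft`, `included`, `total_count` (valid
#'   pairs in the window, before the CPP-range discard) and
#'   `window_length`.
#' @export
bin_window <- function(cpp, prx_ft, window_length, at,
                       config = cppopt_config()) {
  stopifnot(inherits(cpp, "sampled_series"), inherits(prx_ft, "sampled_series"))
  if (cpp$dt != prx_ft$dt || length(cpp) != length(prx_ft) ||
      abs(as.numeric(difftime(cpp$start_time, prx_ft$start_time,
                              units = "secs"))) > 1e-6)
    stop("cpp and prx_ft series are not aligned", call. = FALSE)
  off <- if (inherits(at, "POSIXct"))
    as.numeric(difftime(at, cpp$start_time, units = "secs")) else as.numeric(at)
  tim <- (seq_along(cpp$values) - 1) * cpp$dt
  j <- which(tim > off - window_length & tim <= off &
               cpp$valid & prx_ft$valid)
  make_binned_curve(cpp$values[j], prx_ft$values[j], window_length, config)
}

make_binned_curve <- function(cppv, prxv, window_length, config) {
  edges <- seq(config$bin_min, config$bin_max, length.out = config$n_bins + 1L)
  binw <- (config$bin_max - config$bin_min) / config$n_bins
  total <- length(cppv)
  bi <- floor((cppv - config$bin_min) / binw) + 1L
  keep <- bi >= 1L & bi <= config$n_bins & cppv >= config$bin_min &
    cppv < config$bin_max
  bi <- bi[keep]
  counts <- tabulate(bi, config$n_bins)
  scpp <- numeric(config$n_bins); sprx <- numeric(config$n_bins)
  if (length(bi)) {
    sm <- rowsum(cbind(cppv[keep], prxv[keep]), bi)
    gi <- as.integer(rownames(sm))
    scpp[gi] <- sm[, 1]; sprx[gi] <- sm[, 2]
  }
  mean_cpp <- ifelse(counts > 0, scpp / pmax(counts, 1L), NA_real_)
  mean_prx <- ifelse(counts > 0, sprx / pmax(counts, 1L), NA_real_)
  included <- counts > 0 & counts >= config$min_bin_count_frac * total
  structure(
    list(edges = edges, counts = counts, mean_cpp = mean_cpp,
         mean_prx_ft = mean_prx, included = included, total_count = total,
         window_length = window_length),
    class = "binned_curve"
  )
}

#' Coefficient of determination over all non-empty bins
#'
#' `R^2_full` of a fitted parabola, evaluated against the bin-mean PRx_ft
#' of *all* non-empty CPP bins -- including bins excluded from the curve
#' fit. Penalizing the fit on data it was not allowed to see is what makes
#' this a useful confidence score: a parabola that only explains the bins
#' it was fitted to scores poorly. Floored at 0; degenerate bin sets with
#' zero across-bin variance score 0.
#'
#' @param curve a `binned_curve` (see [bin_window()]).
#' @param coefficients numeric `c(a, b, c)` of `y = a x^2 + b x + c` with
#'   `x` in mmHg.
#' @return R^2 in `[0, 1]`.
#' @export
r2_full <- function(curve, coefficients) {
  nz <- which(curve$counts > 0)
  if (length(nz) < 2L)
    stop("r2_full needs at least 2 non-empty bins", call. = FALSE)
  obs <- curve$mean_prx_ft[nz]
  x <- curve$mean_cpp[nz]
  yhat <- coefficients[1] * x^2 + coefficients[2] * x + coefficients[3]
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot <= 0) return(0)
  max(0, 1 - sum((obs - yhat)^2) / ss_tot)
}

REJECTION_REASONS <- c("missing_data", "data_count", "insufficient_bins",
                       "degenerate_fit", "non_parabolic", "y_span",
                       "y_region", "r2_full")

#' Fit a parabola to one binned window and judge it
#'
#' Least-squares quadratic `PRx_ft = a CPP^2 + b CPP + c` on the included
#' bins' (mean CPP, mean PRx_ft), followed by the acceptance-criteria
#' pipeline in fixed order:
#'
#' 1. **data count** -- the included bins must jointly cover at least
#'    `min_included_frac` (50%) of the window's valid data;
#' 2. **shape** -- "parabolic" means the fitted curve opens upward
#'    (`a > 0`) *and* its vertex lies within the included bins' mean-CPP
#'    range (a nadir outside the observed CPP range is not an observed
#'    optimum);
#' 3. **Y span** -- the fitted curve must span at least `min_y_span` (0.2)
#'    PRx_ft units over the included CPP range (flatter curves carry no
#'    optimum information);
#' 4. **Y region** -- the fitted value range must overlap
#'    `[y_region_min, y_region_max]` = (-0.3, 0.6): no CPPopt is returned
#'    when PRx is uniformly very high (reactivity lost everywhere) or
#'    uniformly very low (preserved everywhere);
#' 5. **R^2_full** -- [r2_full()] must reach `r2_full_min` (0.2); skipped
#'    when the criterion is disabled (`NA`, the previous algorithm).
#'
#' The first failing criterion is recorded as `rejection_reason`; the
#' order affects only that label, never the verdict. Fewer than 3 included
#' bins cannot support a quadratic: `shape = "no-fit"`. All failures are
#' verdicts, not errors. The candidate optimum is the vertex `-b / (2a)`,
#' present iff the shape is parabolic and every criterion passes.
#'
#' @param curve a `binned_curve` from [bin_window()].
#' @param total_count valid-pair count of the window (defaults to the
#'   count recorded in `curve`).
#' @param config a [cppopt_config()].
#' @return A `window_fit`: list with `window_length`, `coefficients`
#'   (a, b, c), `r2_full`, `rmse` (included-bin residual RMSE), `shape`
#'   (`"parabolic"`, `"non-parabolic"`, `"no-fit"`), `candidate_opt`
#'   (mmHg or `NA`), `rejection_reason` (`NA` when accepted),
#'   `n_included`, and `weight` (see [window_weight()]).
#' @export
fit_and_judge <- function(curve, total_count = curve$total_count,
                          config = cppopt_config()) {
  inc <- which(curve$included & curve$counts > 0)
  fit <- list(window_length = curve$window_length,
              coefficients = c(a = NA_real_, b = NA_real_, c = NA_real_),
              r2_full = NA_real_, rmse = NA_real_, shape = "no-fit",
              candidate_opt = NA_real_, rejection_reason = NA_character_,
              n_included = length(inc), weight = 0)
  class(fit) <- "window_fit"
  reason <- NA_character_
  if (total_count <= 0 ||
      sum(curve$counts[inc]) < config$min_included_frac * total_count)
    reason <- "data_count"
  if (length(inc) < 3L) {
    fit$rejection_reason <- if (is.na(reason)) "insufficient_bins" else reason
    return(fit)
  }
  x <- curve$mean_cpp[inc]
  y <- curve$mean_prx_ft[inc]
  # center and scale the abscissa for conditioning; map back afterwards
  x0 <- (config$bin_min + config$bin_max) / 2
  s <- (config$bin_max - config$bin_min) / 2
  u <- (x - x0) / s
  X <- cbind(1, u, u * u)
  beta <- tryCatch(solve(crossprod(X), crossprod(X, y)),
                   error = function(e) NULL)
  if (is.null(beta) || any(!is.finite(beta))) {
    fit$rejection_reason <- if (is.na(reason)) "degenerate_fit" else reason
    return(fit)
  }
  beta <- as.numeric(beta)
  a <- beta[3] / s^2
  b <- beta[2] / s - 2 * beta[3] * x0 / s^2
  cc <- beta[1] - beta[2] * x0 / s + beta[3] * x0^2 / s^2
  fit$coefficients <- c(a = a, b = b, c = cc)
  yhat <- X %*% beta
  fit$rmse <- sqrt(mean((y - yhat)^2))
  fit$r2_full <- r2_full(curve, fit$coefficients)
  # shape classification
  vertex <- if (a > 0) -b / (2 * a) else NA_real_
  xlo <- min(x); xhi <- max(x)
  parabolic <- a > 0 && !is.na(vertex) && vertex >= xlo && vertex <= xhi
  fit$shape <- if (parabolic) "parabolic" else "non-parabolic"
  # fitted-curve value range over the included CPP range
  f <- function(z) a * z^2 + b * z + cc
  vals <- c(f(xlo), f(xhi), if (a != 0 && -b / (2 * a) >= xlo &&
                                -b / (2 * a) <= xhi) f(-b / (2 * a)))
  fmin <- min(vals); fmax <- max(vals)
  if (is.na(reason) && !parabolic) reason <- "non_parabolic"
  if (is.na(reason) && (fmax - fmin) < config$min_y_span) reason <- "y_span"
  if (is.na(reason) && (fmin > config$y_region_max ||
                        fmax < config$y_region_min)) reason <- "y_region"
  if (is.na(reason) && !is.na(config$r2_full_min) &&
      fit$r2_full < config$r2_full_min) reason <- "r2_full"
  fit$rejection_reason <- reason
  if (is.na(reason)) fit$candidate_opt <- vertex
  fit$weight <- window_weight(fit, config)
  fit
}

#' @export
print.window_fit <- function(x, ...) {
  cat(sprintf("<window_fit> %.0f s window: %s", x$window_length %||% NA,
              x$shape))
  if (!is.na(x$candidate_opt))
    cat(sprintf(", CPPopt %.1f mmHg, R2_full %.2f, weight %.3f\n",
                x$candidate_opt, x$r2_full, x$weight))
  else
    cat(sprintf(", rejected (%s)\n", x$rejection_reason))
  invisible(x)
}

#' Weight of one window's candidate optimum
#'
#' New scheme: `weight = R^2_full` for an accepted parabolic fit, 0
#' otherwise -- the fit's confidence over all bins is the weighting
#' factor. Previous scheme: `weight = exp(-L) * exp(-rmse) * w_np`, with
#' `L` the window length in hours, `rmse` the included-bin residual RMSE
#' in Fisher-transformed PRx units, and `w_np` 1 for parabolic, 0 for
#' non-parabolic fits (the historical formula leaves its units unstated;
#' these conventions are documented in the methods vignette). Under both
#' schemes the weight is 0 whenever no candidate optimum was produced.
#'
#' @param fit a `window_fit` from [fit_and_judge()].
#' @param config a [cppopt_config()].
#' @return non-negative scalar weight.
#' @export
window_weight <- function(fit, config = cppopt_config()) {
  if (is.na(fit$candidate_opt)) return(0)
  if (config$weighting == "new") return(fit$r2_full)
  if (is.null(fit$window_length) || is.na(fit$window_length))
    stop("previous-scheme weighting needs the fit's window_length",
         call. = FALSE)
  exp(-fit$window_length / 3600) * exp(-fit$rmse)
}

#' Combine candidate optima from all windows of one update tick
#'
#' Weighted average of the candidate optima over fits with positive
#' weight; absent (`NA`) when no window contributed.
#'
#' @param fits list of `window_fit` objects from one update tick.
#' @return list with `cppopt` (mmHg, or `NA`) and `contributing` (count
#'   of positive-weight windows).
#' @export
combine_windows <- function(fits) {
  w <- vapply(fits, function(f) f$weight, numeric(1))
  o <- vapply(fits, function(f) f$candidate_opt, numeric(1))
  pos <- which(w > 0 & !is.na(o))
  if (!length(pos) || sum(w[pos]) <= 0)
    return(list(cppopt = NA_real_, contributing = 0L))
  list(cppopt = sum(w[pos] * o[pos]) / sum(w[pos]),
       contributing = length(pos))
}

#' Exponentially weighted average of the raw CPPopt trend
#'
#' At each tick the output is the weighted mean of the valid raw samples
#' in the trailing `ewa_window` buffer, with weight `(1 - alpha)^k` for a
#' sample `k` ticks back -- more recent values contribute more. Invalid
#' when the buffer holds no valid raw sample.
#'
#' @param raw raw CPPopt [sampled_series()] at the update cadence.
#' @param config a [cppopt_config()].
#' @return A [sampled_series()] on the same grid.
#' @export
ewa_smooth <- function(raw, config = cppopt_config()) {
  stopifnot(inherits(raw, "sampled_series"))
  K <- as.integer(round(config$ewa_window / raw$dt))
  wk <- (1 - config$ewa_alpha)^(0:(K - 1L))
  n <- length(raw)
  out <- rep(NA_real_, n)
  v <- raw$valid; x <- raw$values
  for (i in seq_len(n)) {
    j <- i:max(1L, i - K + 1L)          # ages 0, 1, ...
    sel <- v[j]
    if (!any(sel)) next
    w <- wk[seq_along(j)][sel]
    out[i] <- sum(w * x[j][sel]) / sum(w)
  }
  sampled_series(out, raw$dt, raw$start_time, valid = !is.na(out))
}

#' Minute-by-minute multi-window weighted CPPopt
#'
#' The full pipeline: CPP = ABP - ICP at the input cadence; CPP
#' pre-filtered with the configured trailing 5-min statistic; PRx via
#' [compute_prx()] and Fisher transform; then, at every minute tick past
#' warm-up, each of the 36 look-back windows is binned ([bin_window()]),
#' fitted and judged ([fit_and_judge()]), weighted ([window_weight()])
#' and the accepted nadirs combined ([combine_windows()]); the raw trend
#' is finally smoothed with a 2-h exponentially weighted average
#' ([ewa_smooth()]).
#'
#' Warm-up: no output is produced until the accumulated valid input time
#' inside the maximal (8-h) look-back buffer reaches `missing_data_limit`
#' of it -- at defaults, 4 h of continuously acquired data are necessary
#' to generate the first CPPopt value. Each individual window is
#' additionally skipped when more than `missing_data_limit` of its own
#' span is missing. Input shorter than the warm-up yields an all-invalid
#' trend with `warmed_up = FALSE`, not an error.
#'
#' @param abp10,icp10 aligned [sampled_series()] of arterial blood
#'   pressure and intracranial pressure (mmHg), conventionally 10-s
#'   averages.
#' @param config a [cppopt_config()].
#' @return A `cppopt_trend`: list with `cpp` (pre-filtered minute CPP),
#'   `prx`, `prx_ft`, `raw` and `smoothed` CPPopt [sampled_series()] at
#'   the update cadence, `contributing` (windows per tick),
#'   `rejection_summary` (per-tick "reason:count" strings), `config`, and
#'   `warmed_up`.
#' @examples
#' \donttest{
#' spec <- virtual_patient_spec(duration = 6 * 3600, seed = 1)
#' rec <- simulate_patient(spec)
#' tr <- compute_cppopt(rec$abp10, rec$icp10, cppopt_config())
#' tr
#' }
#' @export
compute_cppopt <- function(abp10, icp10, config = cppopt_config()) {
  stopifnot(inherits(abp10, "sampled_series"),
            inherits(icp10, "sampled_series"),
            inherits(config, "cppopt_config"))
  if (abp10$dt != icp10$dt || length(abp10) != length(icp10) ||
      abs(as.numeric(difftime(abp10$start_time, icp10$start_time,
                              units = "secs"))) > 1e-6)
    stop("ABP and ICP series are not aligned", call. = FALSE)
  if (config$prx_cadence != config$update_cadence)
    stop("prx_cadence must equal update_cadence", call. = FALSE)
  dt <- abp10$dt
  kc <- config$update_cadence / dt
  if (abs(kc - round(kc)) > 1e-9)
    stop("update_cadence must be an integer multiple of the input dt",
         call. = FALSE)
  kc <- as.integer(round(kc))
  n10 <- length(abp10)
  M <- (n10 - 1L) %/% kc                 # minute ticks 1..M
  cadence <- config$update_cadence
  t1 <- abp10$start_time + cadence
  empty <- sampled_series(rep(NA_real_, max(M, 0L)), cadence, t1)
  if (M < 1L)
    return(new_cppopt_trend(empty, empty, empty, empty, empty,
                            integer(0), character(0), config, FALSE))

  pv10 <- abp10$valid & icp10$valid
  cppv10 <- abp10$values - icp10$values
  cpp10 <- sampled_series(cppv10, dt, abp10$start_time, valid = pv10)

  # pre-filtered CPP, evaluated at minute ticks only
  kf <- as.integer(round(config$cpp_prefilter_window / dt))
  tick_idx <- seq_len(M) * kc + 1L
  cpp60v <- trailing_stat_at(cpp10, kf, config$cpp_prefilter, tick_idx)
  cpp60 <- sampled_series(cpp60v, cadence, t1)

  prx <- compute_prx(abp10, icp10, window = config$prx_window,
                     cadence = config$prx_cadence,
                     min_pairs = config$prx_min_pairs)
  stopifnot(length(prx$prx_ft) == M)

  # warm-up gate: valid input seconds in the maximal look-back buffer
  cv <- cumsum(as.numeric(pv10))
  kwmax <- as.integer(round(config$window_max / dt))
  i0 <- pmax(tick_idx - kwmax, 0L)
  valid_sec <- (cv[tick_idx] - ifelse(i0 > 0L, cv[i0], 0)) * dt
  gate <- valid_sec >= config$missing_data_limit * config$window_max

  lens <- enumerate_windows(config)
  res <- engine_ticks(cpp60, prx$prx_ft, gate, lens, config)

  raw <- sampled_series(res$raw, cadence, t1, valid = !is.na(res$raw))
  smoothed <- ewa_smooth(raw, config)
  new_cppopt_trend(cpp60, prx$prx, prx$prx_ft, raw, smoothed,
                   res$contributing, res$rejection_summary, config,
                   any(gate))
}

new_cppopt_trend <- function(cpp, prx, prx_ft, raw, smoothed, contributing,
                             rejection_summary, config, warmed_up) {
  structure(
    list(cpp = cpp, prx = prx, prx_ft = prx_ft, raw = raw,
         smoothed = smoothed, contributing = contributing,
         rejection_summary = rejection_summary, config = config,
         warmed_up = warmed_up),
    class = "cppopt_trend"
  )
}

# Per-tick multi-window fitting. Shares exact binning semantics with
# bin_window(); when every window length is a multiple of window_step the
# per-bin sums are accumulated once per tick over 10-min age chunks and
# cumulated across chunks, which serves all 36 windows in one pass.
engine_ticks <- function(cpp60, prx_ft60, gate, lens, config) {
  M <- length(cpp60)
  cadence <- cpp60$dt
  raw <- rep(NA_real_, M)
  contributing <- integer(M)
  rejection_summary <- character(M)
  pairv <- cpp60$valid & prx_ft60$valid
  cppv <- cpp60$values
  prxv <- prx_ft60$values
  binw <- (config$bin_max - config$bin_min) / config$n_bins
  nb <- config$n_bins
  binix <- rep(0L, M)
  ok <- pairv & cppv >= config$bin_min & cppv < config$bin_max
  binix[ok] <- pmin(floor((cppv[ok] - config$bin_min) / binw) + 1L, nb)
  edges <- seq(config$bin_min, config$bin_max, length.out = nb + 1L)

  Lm <- as.integer(round(lens / cadence))          # window lengths in ticks
  step_m <- as.integer(round(config$window_step / cadence))
  fast <- step_m >= 1L && all(Lm %% step_m == 0L)
  A <- max(Lm)
  nchunk <- if (fast) A %/% step_m else 0L

  for (m in which(gate)) {
    fits <- vector("list", length(lens))
    if (fast) {
      ages <- 0:(min(A, m) - 1L)
      idx <- m - ages
      ch <- ages %/% step_m + 1L
      pvw <- pairv[idx]
      vc <- tabulate(ch[pvw], nchunk)
      cum_valid <- cumsum(vc)
      sel <- binix[idx] > 0L
      g <- binix[idx][sel] + nb * (ch[sel] - 1L)
      cnt <- tabulate(g, nb * nchunk)
      dim(cnt) <- c(nb, nchunk)
      scpp <- matrix(0, nb, nchunk); sprx <- matrix(0, nb, nchunk)
      if (any(sel)) {
        sm <- rowsum(cbind(cppv[idx][sel], prxv[idx][sel]), g)
        gi <- as.integer(rownames(sm))
        scpp[gi] <- sm[, 1]; sprx[gi] <- sm[, 2]
      }
      ccnt <- t(apply(cnt, 1L, cumsum))
      cscpp <- t(apply(scpp, 1L, cumsum))
      csprx <- t(apply(sprx, 1L, cumsum))
      for (j in seq_along(lens)) {
        kch <- Lm[j] %/% step_m
        total <- cum_valid[kch]
        if (total < config$missing_data_limit * Lm[j]) {
          fits[[j]] <- missing_data_fit(lens[j])
          next
        }
        counts <- ccnt[, kch]
        mean_cpp <- ifelse(counts > 0, cscpp[, kch] / pmax(counts, 1L),
                           NA_real_)
        mean_prx <- ifelse(counts > 0, csprx[, kch] / pmax(counts, 1L),
                           NA_real_)
        included <- counts > 0 & counts >= config$min_bin_count_frac * total
        curve <- structure(
          list(edges = edges, counts = counts, mean_cpp = mean_cpp,
               mean_prx_ft = mean_prx, included = included,
               total_count = total, window_length = lens[j]),
          class = "binned_curve")
        fits[[j]] <- fit_and_judge(curve, total, config)
      }
    } else {
      for (j in seq_along(lens)) {
        # tick m sits at offset (m - 1) * cadence from the series start
        curve <- bin_window(cpp60, prx_ft60, lens[j], (m - 1) * cadence,
                            config)
        if (curve$total_count <
            config$missing_data_limit * Lm[j]) {
          fits[[j]] <- missing_data_fit(lens[j])
        } else {
          fits[[j]] <- fit_and_judge(curve, curve$total_count, config)
        }
      }
    }
    comb <- combine_windows(fits)
    raw[m] <- comb$cppopt
    contributing[m] <- comb$contributing
    reasons <- vapply(fits, function(f) f$rejection_reason %||% NA_character_,
                      character(1))
    tab <- table(factor(reasons, levels = REJECTION_REASONS))
    tab <- tab[tab > 0]
    rejection_summary[m] <-
      if (length(tab)) paste(names(tab), tab, sep = ":", collapse = ";") else ""
  }
  list(raw = raw, contributing = contributing,
       rejection_summary = rejection_summary)
}

missing_data_fit <- function(window_length) {
  structure(
    list(window_length = window_length,
         coefficients = c(a = NA_real_, b = NA_real_, c = NA_real_),
         r2_full = NA_real_, rmse = NA_real_, shape = "no-fit",
         candidate_opt = NA_real_, rejection_reason = "missing_data",
         n_included = 0L, weight = 0),
    class = "window_fit")
}

#' @export
print.cppopt_trend <- function(x, ...) {
  n <- length(x$smoothed)
  nv <- sum(x$smoothed$valid)
  cat(sprintf("<cppopt_trend> variant '%s', %d minute ticks, %d with CPPopt (%.1f%%)\n",
              x$config$variant, n, nv, if (n) 100 * nv / n else 0))
  if (nv) {
    fv <- which(x$smoothed$valid)[1]
    cat(sprintf("  first CPPopt at %.1f h; smoothed range %.1f-%.1f mmHg\n",
                fv * x$smoothed$dt / 3600,
                min(x$smoothed$values[x$smoothed$valid]),
                max(x$smoothed$values[x$smoothed$valid])))
  } else if (!x$warmed_up) {
    cat("  warm-up not reached (input shorter than required valid time)\n")
  }
  invisible(x)
}

#' @export
as.data.frame.cppopt_trend <- function(x, row.names = NULL, optional = FALSE,
                                       ...) {
  data.frame(
    datetime = series_times(x$smoothed),
    cpp = masked_values(x$cpp),
    prx = masked_values(x$prx),
    prx_ft = masked_values(x$prx_ft),
    cppopt_raw = masked_values(x$raw),
    cppopt = masked_values(x$smoothed),
    n_windows = x$contributing,
    rejection_summary = x$rejection_summary
  )
}

#' Write a CPPopt trend to delimited text
#'
#' @param trend a `cppopt_trend` from [compute_cppopt()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trend <- function(trend, path) {
  df <- as.data.frame(trend)
  df$datetime <- format(df$datetime, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}
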