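# Shared fixtures, built in code and cached for the duration of one test
# run (several tests reuse the same 10-h engine runs).
.fx <- new.env(parent = emptyenv())

fx <- function(key, build) {
  if (!exists(key, envir = .fx, inherits = FALSE))
    assign(key, build(), envir = .fx)
  get(key, envir = .fx, inherits = FALSE)
}

ss <- function(values, dt = 60, valid = !is.na(values), ...) {
  sampled_series(values, dt, valid = valid, ...)
}

# canonical 10-h gap-free virtual patient + both variant trends
fx_patient <- function(seed = 42, true_opt = 75, duration = 36000, ...) {
  fx(sprintf("pat_%d_%g_%g", seed, true_opt, duration), function()
    simulate_patient(virtual_patient_spec(duration = duration,
                                          true_opt = true_opt,
                                          seed = seed, ...)))
}

fx_trend <- function(variant = "new", seed = 42) {
  fx(sprintf("trend_%s_%d", variant, seed), function() {
    rec <- fx_patient(seed)
    compute_cppopt(rec$abp10, rec$icp10, cppopt_config(variant))
  })
}

# a short recording that still clears the 4-h warm-up, for cheap tests
fx_short_trend <- function(variant = "new") {
  fx(paste0("short_", variant), function() {
    rec <- fx_patient(7, duration = 5.5 * 3600)
    compute_cppopt(rec$abp10, rec$icp10, cppopt_config(variant))
  })
}

# build a binned_curve directly from per-bin data, as fit_and_judge
# consumes it (bypasses the time dimension)
curve_from_bins <- function(mean_cpp, mean_prx_ft, counts,
                            cfg = cppopt_config(), window_length = 7200) {
  nb <- cfg$n_bins
  edges <- seq(cfg$bin_min, cfg$bin_max, length.out = nb + 1L)
  cnt <- integer(nb); mc <- rep(NA_real_, nb); mp <- rep(NA_real_, nb)
  bi <- findInterval(mean_cpp, edges, rightmost.closed = FALSE)
  stopifnot(!anyDuplicated(bi))
  cnt[bi] <- counts; mc[bi] <- mean_cpp; mp[bi] <- mean_prx_ft
  total <- sum(counts)
  structure(list(edges = edges, counts = cnt, mean_cpp = mc,
                 mean_prx_ft = mp,
                 included = cnt > 0 & cnt >= cfg$min_bin_count_frac * total,
                 total_count = total, window_length = window_length),
            class = "binned_curve")
}

# last-2-h median of the smoothed trend, NA when nothing is available
final_median <- function(trend, hours = 2) {
  n <- length(trend$smoothed)
  k <- as.integer(hours * 3600 / trend$smoothed$dt)
  i <- which(trend$smoothed$valid & seq_len(n) > n - k)
  if (!length(i)) return(NA_real_)
  stats::median(trend$smoothed$values[i])
}
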