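test_that("enumerate_windows yields 36 windows ending at 8 h, validates input", {
  w <- enumerate_windows(cppopt_config())
  expect_length(w, 36)
  expect_equal(w[length(w)], 28800)
  expect_true(all(diff(w) == 600))
  expect_equal(enumerate_windows(cppopt_config(n_windows = 1L,
                                               window_min = 7200,
                                               window_max = 7200)), 7200)
  expect_error(cppopt_config(n_windows = 37L), "inconsistent window quadruple")
})

test_that("configuration presets and validation behave", {
  new <- cppopt_config()
  prev <- cppopt_config("previous")
  expect_equal((new$bin_max - new$bin_min) / new$n_bins, 5)
  expect_equal(new$min_bin_count_frac, 0.03)
  expect_equal(prev$min_bin_count_frac, 0.02)
  expect_true(is.na(prev$r2_full_min))
  expect_identical(prev$cpp_prefilter, "mean")
  expect_error(cppopt_config(no_such_field = 1), "unknown configuration")
  expect_error(cppopt_config(ewa_alpha = 1.2), "ewa_alpha")
  expect_error(cppopt_config(bin_min = 130), "bin_min")
})

test_that("bin_window uses half-open bins and the bin-count threshold", {
  cfg <- cppopt_config()
  cpp <- ss(rep(72.3, 100))
  prx <- ss(rnorm(100, 0.1, 0.01))
  cu <- bin_window(cpp, prx, 7200, 6000, cfg)
  expect_equal(sum(cu$counts), 100)
  expect_equal(which(cu$counts > 0), 7L)   # [70, 75)
  expect_equal(cu$total_count, 100)
  # a bin holding 2 of 100 samples: excluded at 3%, included at 1-2%
  cpp2 <- ss(c(rep(72.3, 98), 81, 81.2))
  cu3 <- bin_window(cpp2, ss(rnorm(100)), 7200, 6000, cppopt_config())
  cu2 <- bin_window(cpp2, ss(rnorm(100)), 7200, 6000, cppopt_config("previous"))
  expect_false(cu3$included[9])
  expect_true(cu2$included[9])
  # CPP outside [bin_min, bin_max) is discarded but still counts in total
  cpp3 <- ss(c(rep(72.3, 50), rep(125, 25), rep(30, 25)))
  cu4 <- bin_window(cpp3, ss(rnorm(100)), 7200, 6000, cfg)
  expect_equal(sum(cu4$counts), 50)
  expect_equal(cu4$total_count, 100)
  # empty window: all-empty bins, not an error
  cu5 <- bin_window(ss(numeric(0)), ss(numeric(0)), 7200, 6000, cfg)
  expect_true(all(cu5$counts == 0))
})

test_that("fit_and_judge recovers a constructed parabola exactly", {
  cfg <- cppopt_config()
  x <- seq(50, 90, by = 5) + 2.5
  y <- 0.001 * (x - 70)^2 - 0.1
  cu <- curve_from_bins(x, y, rep(50, length(x)), cfg)
  f <- fit_and_judge(cu, cu$total_count, cfg)
  expect_identical(f$shape, "parabolic")
  expect_equal(f$candidate_opt, 70, tolerance = 1e-8)
  expect_equal(f$r2_full, 1, tolerance = 1e-10)
  expect_true(is.na(f$rejection_reason))
  expect_gte(f$candidate_opt, cfg$bin_min)
  expect_lte(f$candidate_opt, cfg$bin_max)
  expect_equal(f$weight, f$r2_full)
})

test_that("fit_and_judge rejection pipeline fires in documented order", {
  cfg <- cppopt_config()
  x <- seq(52.5, 87.5, by = 5)
  # bins on a line: non-parabolic, weight 0
  lin <- curve_from_bins(x, 0.01 * x - 0.5, rep(40, length(x)), cfg)
  fl <- fit_and_judge(lin, lin$total_count, cfg)
  expect_identical(fl$shape, "non-parabolic")
  expect_identical(fl$rejection_reason, "non_parabolic")
  expect_equal(fl$weight, 0)
  expect_true(is.na(fl$candidate_opt))
  # flat parabola: fitted span well under 0.2 -> y_span
  yf <- 0.1 * ((x - 70) / 20)^2 - 0.05
  flat <- curve_from_bins(x, yf, rep(40, length(x)), cfg)
  ff <- fit_and_judge(flat, flat$total_count, cfg)
  expect_identical(ff$rejection_reason, "y_span")
  # curve entirely above 0.7 -> y_region
  hi <- curve_from_bins(x, 0.001 * (x - 70)^2 + 0.75, rep(40, length(x)), cfg)
  fh <- fit_and_judge(hi, hi$total_count, cfg)
  expect_identical(fh$rejection_reason, "y_region")
  # included bins covering < 50% of the window total -> data_count first
  low <- curve_from_bins(x, 0.001 * (x - 70)^2 - 0.1, rep(40, length(x)), cfg)
  fd <- fit_and_judge(low, total_count = sum(low$counts) * 3, cfg)
  expect_identical(fd$rejection_reason, "data_count")
  # under 3 included bins -> no-fit
  tiny <- curve_from_bins(c(62.5, 67.5), c(0, 0.1), c(50, 50), cfg)
  ft <- fit_and_judge(tiny, tiny$total_count, cfg)
  expect_identical(ft$shape, "no-fit")
  expect_identical(ft$rejection_reason, "insufficient_bins")
  # r2_full gate: parabolic included bins, contradicted by excluded bins
  x6 <- c(52.5, 57.5, 62.5, 67.5, 72.5, 77.5)
  y6 <- 0.004 * (x6 - 65)^2 - 0.25
  y6[c(1, 6)] <- y6[c(1, 6)] + c(2, -2)     # off-curve, tiny counts
  contra <- curve_from_bins(x6, y6, c(2, 300, 300, 300, 300, 2), cfg)
  fc <- fit_and_judge(contra, contra$total_count, cfg)
  expect_identical(fc$rejection_reason, "r2_full")
  expect_lt(fc$r2_full, 0.2)
  # same curve passes when the criterion is disabled (previous algorithm)
  cfgp <- cppopt_config("previous")
  contra_p <- curve_from_bins(x6, y6, c(2, 300, 300, 300, 300, 2), cfgp)
  fp <- fit_and_judge(contra_p, contra_p$total_count, cfgp)
  expect_true(is.na(fp$rejection_reason))
})

test_that("r2_full penalizes bins excluded from the fit", {
  cfg <- cppopt_config()
  x <- c(52.5, 57.5, 62.5, 67.5, 72.5)
  y <- 0.002 * (x - 62.5)^2 - 0.2
  on_curve <- curve_from_bins(x, y, rep(100, 5), cfg)
  f <- fit_and_judge(on_curve, on_curve$total_count, cfg)
  expect_equal(r2_full(on_curve, f$coefficients), 1, tolerance = 1e-10)
  # add one excluded bin far off the curve: r2_full < included-bin r2
  x2 <- c(x, 82.5); y2 <- c(y, 1.5)
  off <- curve_from_bins(x2, y2, c(rep(100, 5), 3), cfg)
  f2 <- fit_and_judge(off, off$total_count, cfg)
  inc <- which(off$included)
  yhat <- f2$coefficients[1] * off$mean_cpp[inc]^2 +
    f2$coefficients[2] * off$mean_cpp[inc] + f2$coefficients[3]
  r2_inc <- 1 - sum((off$mean_prx_ft[inc] - yhat)^2) /
    sum((off$mean_prx_ft[inc] - mean(off$mean_prx_ft[inc]))^2)
  expect_lt(r2_full(off, f2$coefficients), r2_inc)
  # zero across-bin variance -> 0 by contract
  flat <- curve_from_bins(x, rep(0.1, 5), rep(100, 5), cfg)
  expect_equal(r2_full(flat, c(0, 0, 0.1)), 0)
  expect_error(r2_full(curve_from_bins(62.5, 0.1, 10, cfg), c(0, 0, 0)),
               "2 non-empty bins")
})

test_that("window_weight implements both schemes", {
  cfg <- cppopt_config()
  acc <- list(window_length = 7200, candidate_opt = 75, r2_full = 0.8,
              rmse = 0.05, shape = "parabolic")
  expect_equal(window_weight(acc, cfg), 0.8)
  rej <- acc; rej$candidate_opt <- NA_real_
  expect_equal(window_weight(rej, cfg), 0)
  cfgp <- cppopt_config("previous")
  perfect <- acc; perfect$rmse <- 0
  expect_equal(window_weight(perfect, cfgp), exp(-2))   # 2-h window, rmse 0
  expect_equal(window_weight(acc, cfgp), exp(-2) * exp(-0.05))
})

test_that("combine_windows is a weighted mean over positive weights", {
  wf <- function(opt, w) list(candidate_opt = opt, weight = w)
  expect_equal(combine_windows(list(wf(75, 0.4)))$cppopt, 75)
  expect_equal(combine_windows(list(wf(70, 1), wf(80, 1)))$cppopt, 75)
  expect_equal(combine_windows(list(wf(70, 0.2), wf(80, 0.6)))$cppopt, 77.5)
  none <- combine_windows(list(wf(NA, 0), wf(70, 0)))
  expect_true(is.na(none$cppopt))
  expect_equal(none$contributing, 0L)
})

test_that("ewa_smooth matches hand computations and validity rules", {
  cfg <- cppopt_config()
  cst <- ewa_smooth(ss(rep(75, 130)), cfg)
  expect_equal(cst$values[cst$valid], rep(75, 130))
  single <- ewa_smooth(ss(c(rep(NA, 10), 80)), cfg)
  expect_equal(single$values[11], 80)
  expect_equal(sum(single$valid), 1L)
  two <- ewa_smooth(ss(c(70, 80)), cfg)
  expect_equal(two$values[2], (80 + 0.9 * 70) / 1.9)
  # beyond the 2-h buffer the old sample stops contributing
  far <- ewa_smooth(ss(c(70, rep(NA, 120), 80)), cfg)
  expect_equal(far$values[122], 80)       # the 70 has aged out of the buffer
  expect_false(far$valid[121])            # buffer holds no valid sample
})

test_that("engine matches the bin_window/fit_and_judge path tick by tick", {
  tr <- fx_short_trend("new")
  cfg <- tr$config
  lens <- enumerate_windows(cfg)
  for (m in c(245, 280, 320)) {
    fits <- lapply(lens, function(L) {
      # tick m sits at offset (m - 1) * 60 from the trend series start
      cu <- bin_window(tr$cpp, tr$prx_ft, L, (m - 1) * 60, cfg)
      if (cu$total_count < cfg$missing_data_limit * L / 60)
        return(list(candidate_opt = NA_real_, weight = 0))
      fit_and_judge(cu, cu$total_count, cfg)
    })
    comb <- combine_windows(fits)
    if (is.na(comb$cppopt)) {
      expect_false(tr$raw$valid[m])
    } else {
      expect_equal(tr$raw$values[m], comb$cppopt, tolerance = 1e-10)
      expect_equal(tr$contributing[m], comb$contributing)
    }
  }
})

test_that("engine slow path (non-chunked windows) agrees with bin_window", {
  rec <- fx_patient(7, duration = 5.5 * 3600)
  cfg <- cppopt_config(window_min = 7500, window_max = 9300,
                       window_step = 600, n_windows = 3L)
  tr <- compute_cppopt(rec$abp10, rec$icp10, cfg)
  m <- which(tr$raw$valid)[1]
  expect_false(is.na(m))
  fits <- lapply(enumerate_windows(cfg), function(L) {
    cu <- bin_window(tr$cpp, tr$prx_ft, L, (m - 1) * 60, cfg)
    if (cu$total_count < cfg$missing_data_limit * L / 60)
      return(list(candidate_opt = NA_real_, weight = 0))
    fit_and_judge(cu, cu$total_count, cfg)
  })
  expect_equal(tr$raw$values[m], combine_windows(fits)$cppopt,
               tolerance = 1e-10)
})

test_that("warm-up: no output before 4 h, short input is not an error", {
  tr <- fx_short_trend("new")
  iv <- which(tr$smoothed$valid)
  expect_equal(iv[1], 240L)              # 4 h at 60-s cadence
  expect_false(any(tr$raw$valid[seq_len(239)]))
  rec <- fx_patient(5, duration = 2 * 3600)
  short <- compute_cppopt(rec$abp10, rec$icp10, cppopt_config())
  expect_false(short$warmed_up)
  expect_false(any(short$smoothed$valid))
})

test_that("both variants run from one code path and are deterministic", {
  rec <- fx_patient(7, duration = 5.5 * 3600)
  a <- compute_cppopt(rec$abp10, rec$icp10, cppopt_config("previous"))
  b <- compute_cppopt(rec$abp10, rec$icp10, cppopt_config("previous"))
  expect_identical(a$smoothed$values, b$smoothed$values)
  expect_identical(a$raw$valid, b$raw$valid)
  # config-only difference from the new variant
  n <- fx_short_trend("new")
  expect_false(identical(a$smoothed$values, n$smoothed$values))
})

test_that("emitted CPPopt always stays inside the binning range", {
  for (tr in list(fx_short_trend("new"), fx_short_trend("previous"))) {
    for (s in list(tr$raw, tr$smoothed)) {
      v <- s$values[s$valid]
      expect_true(all(v >= tr$config$bin_min & v <= tr$config$bin_max))
    }
  }
})

test_that("trend data frame and CSV writer expose the documented columns", {
  tr <- fx_short_trend("new")
  df <- as.data.frame(tr)
  expect_named(df, c("datetime", "cpp", "prx", "prx_ft", "cppopt_raw",
                     "cppopt", "n_windows", "rejection_summary"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trend(tr, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), length(tr$smoothed))
  expect_equal(back$cppopt[240], tr$smoothed$values[240], tolerance = 1e-6)
})
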