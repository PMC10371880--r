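test_that("sampled_series enforces its invariants", {
  s <- ss(c(1, 2, NA), dt = 10)
  expect_s3_class(s, "sampled_series")
  expect_length(s, 3)
  expect_equal(s$valid, c(TRUE, TRUE, FALSE))
  expect_error(sampled_series(1:3, dt = 0), "positive")
  expect_error(sampled_series(1:3, dt = 10, valid = c(TRUE, FALSE)),
               "identical length")
  tms <- series_times(ss(1:3, dt = 10))
  expect_equal(as.numeric(diff(tms)), c(10, 10))
})

test_that("block_average matches its examples and error contract", {
  expect_equal(block_average(ss(c(1, 2, 3), dt = 1), 3, 0.5)$values, 2)
  s <- sampled_series(c(1, 9e9, 9e9), dt = 1, valid = c(TRUE, FALSE, FALSE))
  expect_false(block_average(s, 3, 0.5)$valid)
  expect_equal(block_average(ss(c(80, 82), dt = 1), 2, 0.5)$values,
               mean(c(80, 82)))
  expect_error(block_average(ss(1:10, dt = 3), 10), "integer multiple")
  expect_error(block_average(ss(1:10, dt = 1), 5, min_fraction = 0), "0, 1")
})

test_that("nested block averages compose when min_fraction = 1", {
  set.seed(11)
  for (rep in 1:5) {
    x <- rnorm(36, 80, 5)
    v <- runif(36) > 0.2
    s <- sampled_series(x, dt = 1, valid = v)
    one_step <- block_average(s, 6, min_fraction = 1)
    two_step <- block_average(block_average(s, 2, min_fraction = 1), 6,
                              min_fraction = 1)
    expect_equal(two_step$values[two_step$valid],
                 one_step$values[one_step$valid])
    expect_equal(two_step$valid, one_step$valid)
  }
})

test_that("moving_filter matches examples, median membership, gaps", {
  cst <- moving_filter(ss(rep(70, 20), dt = 1), 5, "mean")
  expect_true(all(cst$values[cst$valid] == 70))
  med <- moving_filter(ss(c(60, 61, 100, 62, 63), dt = 1), 5, "median")
  expect_equal(med$values[5], 62)
  gap <- sampled_series(rep(1e9, 5), dt = 1, valid = rep(FALSE, 5))
  expect_false(any(moving_filter(gap, 3, "median")$valid))
  expect_error(moving_filter(ss(1:5, dt = 1), 3, "max"), "arg")
  expect_error(moving_filter(ss(1:5, dt = 1), 3, alignment = "centered"),
               "trailing")
  # even-count median is the midpoint of the two central values
  ev <- moving_filter(ss(c(1, 3), dt = 1), 2, "median")
  expect_equal(ev$values[2], 2)
})

test_that("median filter output is an element or midpoint of window values", {
  set.seed(4)
  x <- rnorm(50, 75, 8)
  v <- runif(50) > 0.3
  s <- sampled_series(x, dt = 1, valid = v)
  out <- moving_filter(s, 7, "median")
  for (i in which(out$valid)) {
    w <- sort(x[max(1, i - 6):i][v[max(1, i - 6):i]])
    mids <- if (length(w) > 1) (w[-1] + w[-length(w)]) / 2 else w
    expect_true(min(abs(c(w, mids) - out$values[i])) < 1e-12)
  }
})

test_that("trailing filters agree with a brute-force oracle on gappy data", {
  set.seed(9)
  x <- rnorm(120, 80, 6)
  v <- runif(120) > 0.25
  s <- sampled_series(x, dt = 10, valid = v)
  for (stat in c("mean", "median")) {
    out <- moving_filter(s, 50, stat)
    oracle <- vapply(seq_len(120), function(i) {
      j <- max(1, i - 4):i
      w <- x[j][v[j]]
      if (!length(w)) return(NA_real_)
      if (stat == "mean") mean(w) else median(w)
    }, numeric(1))
    expect_equal(ifelse(out$valid, out$values, NA_real_), oracle)
  }
})

test_that("no operation reads poisoned invalid values", {
  x <- c(80, 81, 82, 83, 84, 85)
  v <- c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE)
  clean <- sampled_series(ifelse(v, x, NA), dt = 10)
  poison <- sampled_series(ifelse(v, x, 1e12), dt = 10, valid = v)
  for (op in list(function(s) block_average(s, 20, 0.4),
                  function(s) moving_filter(s, 30, "mean"),
                  function(s) moving_filter(s, 30, "median"))) {
    a <- op(clean); b <- op(poison)
    expect_equal(a$valid, b$valid)
    expect_equal(a$values[a$valid], b$values[b$valid])
  }
})

test_that("recording round-trips through delimited text", {
  t0 <- as.POSIXct("2026-02-01 08:00:00", tz = "UTC")
  abp <- sampled_series(c(88.25, NA, 90.5, 91), dt = 10, start_time = t0)
  icp <- sampled_series(c(12, 13, NA, 12.5), dt = 10, start_time = t0)
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording(list(`abp[mmHg]` = abp, `icp[mmHg]` = icp), path)
  back <- read_recording(path, dt = 10)
  expect_named(back, c("abp", "icp"))
  expect_equal(back$abp$valid, abp$valid)
  expect_equal(back$abp$values[abp$valid], abp$values[abp$valid])
  expect_equal(back$icp$values[icp$valid], icp$values[icp$valid])
  expect_equal(as.numeric(difftime(back$abp$start_time, t0, units = "secs")), 0)
})

test_that("reader snaps irregular timestamps and averages duplicates", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("datetime,abp[mmHg]",
               "2026-02-01T00:00:00,80",
               "2026-02-01T00:00:11,82",   # snaps to grid point 10
               "2026-02-01T00:00:19,84",   # snaps to grid point 20
               "2026-02-01T00:00:21,86",   # duplicate hit on 20: averaged
               "2026-02-01T00:00:40,90"),  # leaves grid point 30 invalid
             path)
  r <- read_recording(path, dt = 10)$abp
  expect_equal(r$values[r$valid], c(80, 82, 85, 90))
  expect_equal(r$valid, c(TRUE, TRUE, TRUE, FALSE, TRUE))
})
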