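#' Read an ABP/ICP recording from delimited text
#'
#' Expects a CSV (or other single-character-delimited) file with a
#' `datetime` column (ISO-8601) and signal columns `abp[mmHg]` and
#' `icp[mmHg]` (bare `abp`/`icp` are also accepted). Empty cells are
#' invalid samples. Rows are snapped to a uniform grid of step `dt`
#' anchored at the first timestamp; duplicate grid hits are averaged and
#' grid points with no row become invalid samples, so mildly irregular
#' input is regularized at read time.
#'
#' @param path file path.
#' @param dt grid step in seconds (default 10, the cadence PRx consumes).
#' @param sep field separator.
#' @return A named list of [sampled_series()], one per signal column.
#' @export
read_recording <- function(path, dt = 10, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!"datetime" %in% names(df))
    stop("input file has no `datetime` column", call. = FALSE)
  tm <- as.POSIXct(df$datetime, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
  if (anyNA(tm)) stop("unparseable timestamps in `datetime`", call. = FALSE)
  t0 <- tm[1]
  gi <- as.integer(round(as.numeric(difftime(tm, t0, units = "secs")) / dt))
  if (any(gi < 0)) stop("timestamps are not sorted from the first row",
                        call. = FALSE)
  n <- max(gi) + 1L
  sig_cols <- setdiff(names(df), "datetime")
  out <- lapply(sig_cols, function(cn) {
    x <- suppressWarnings(as.numeric(df[[cn]]))
    sm <- rep(0, n); cnt <- rep(0L, n)
    ok <- !is.na(x)
    for (i in which(ok)) {
      g <- gi[i] + 1L
      sm[g] <- sm[g] + x[i]
      cnt[g] <- cnt[g] + 1L
    }
    vals <- ifelse(cnt > 0L, sm / pmax(cnt, 1L), NA_real_)
    sampled_series(vals, dt, t0)
  })
  names(out) <- sub("\\[.*\\]$", "", sig_cols)
  out
}

#' Write one or more aligned series to delimited text
#'
#' Inverse of [read_recording()]: writes a `datetime` column plus one
#' column per series, with invalid samples as empty cells. All series must
#' share start time, cadence and length.
#'
#' @param series named list of [sampled_series()].
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_recording <- function(series, path, sep = ",") {
  stopifnot(is.list(series), length(series) >= 1L,
            !is.null(names(series)), all(nzchar(names(series))))
  ref <- series[[1]]
  for (s in series) {
    stopifnot(inherits(s, "sampled_series"))
    if (s$dt != ref$dt || length(s) != length(ref) ||
        abs(as.numeric(difftime(s$start_time, ref$start_time, units = "secs"))) > 1e-6)
      stop("all series must share start_time, dt and length", call. = FALSE)
  }
  df <- data.frame(datetime = format(series_times(ref), "%Y-%m-%dT%H:%M:%S",
                                     tz = "UTC"))
  for (nm in names(series)) df[[nm]] <- masked_values(series[[nm]])
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}
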