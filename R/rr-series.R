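#' RR-interval series
#'
#' Container for an ordered sequence of RR intervals (the tachogram of beat-to-
#' beat times, in milliseconds). Beat times are the cumulative sum of the
#' intervals in seconds, so beat `k` is placed at the end of interval `k`.
#'
#' @param intervals numeric vector of RR intervals in ms, all strictly positive.
#' @param subject_id optional subject identifier.
#' @param condition optional condition label, `"spontaneous"` or `"slow_paced"`.
#' @return An object of class `rr_series` with elements `intervals` (ms),
#'   `beat_times` (s), `subject_id` and `condition`.
#' @examples
#' rr <- rr_series(c(800, 820, 790))
#' rr$beat_times   # 0.80 1.62 2.41
#' @export
rr_series <- function(intervals, subject_id = NA_character_,
                      condition = NA_character_) {
  intervals <- as.numeric(intervals)
  if (length(intervals) < 1L) stop_frphrv("an rr_series needs at least one interval")
  if (anyNA(intervals) || any(intervals <= 0)) {
    stop_frphrv("RR intervals must be strictly positive and non-missing")
  }
  structure(
    list(intervals = intervals,
         beat_times = cumsum(intervals) / 1000,
         subject_id = as.character(subject_id),
         condition = as.character(condition)),
    class = "rr_series"
  )
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("RR series: %d beats, %.1f s", length(x$intervals),
              x$beat_times[length(x$beat_times)]))
  tags <- c(if (!is.na(x$subject_id)) sprintf("subject %s", x$subject_id),
            if (!is.na(x$condition)) x$condition)
  if (length(tags)) cat(sprintf(" [%s]", paste(tags, collapse = ", ")))
  cat(sprintf("\n  mean RR %.1f ms, range %.0f-%.0f ms\n",
              mean(x$intervals), min(x$intervals), max(x$intervals)))
  invisible(x)
}

#' @export
length.rr_series <- function(x) length(x$intervals)

#' Read an RR-interval text file
#'
#' Reads the plain-text tachogram dialect used throughout the package: one
#' numeric RR interval in milliseconds per line, blank lines skipped, no
#' header.
#'
#' @param path path to the text file.
#' @inheritParams rr_series
#' @return An [rr_series()].
#' @export
read_rr <- function(path, subject_id = NA_character_, condition = NA_character_) {
  if (!file.exists(path)) stop_frphrv("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  if (!any(keep)) stop_frphrv("empty RR file: ", path)
  idx <- which(keep)
  vals <- suppressWarnings(as.numeric(trimws(lines[keep])))
  if (anyNA(vals)) {
    bad <- idx[which(is.na(vals))[1]]
    stop_frphrv(sprintf("non-numeric RR value at line %d of %s: '%s'",
                        bad, path, trimws(lines[bad])))
  }
  rr_series(vals, subject_id = subject_id, condition = condition)
}

#' Write an RR-interval text file
#'
#' @param rr an [rr_series()].
#' @param path output path; one interval in ms per line.
#' @return `path`, invisibly.
#' @export
write_rr <- function(rr, path) {
  stopifnot(inherits(rr, "rr_series"))
  writeLines(format(rr$intervals, digits = 15, trim = TRUE,
                    scientific = FALSE), path)
  invisible(path)
}

#' Remove physiologically implausible beats
#'
#' Drops every interval outside the closed range `[lo, hi]` ms (defaults
#' 333-2000 ms, i.e. 30-180 bpm), the standard artefact screen for skipped
#' beats and false R-peak detections. Surviving intervals keep their order and
#' beat times are re-accumulated; removed beats are not interpolated.
#'
#' @param rr an [rr_series()].
#' @param lo,hi inclusive bounds in ms.
#' @return A list with `rr` (filtered [rr_series()]) and `removed` (count).
#' @export
remove_outliers <- function(rr, lo = 333, hi = 2000) {
  stopifnot(inherits(rr, "rr_series"))
  if (!(lo < hi)) stop_frphrv("lo must be smaller than hi")
  keep <- rr$intervals >= lo & rr$intervals <= hi
  if (!any(keep)) stop_frphrv("all beats removed by the outlier filter")
  out <- rr_series(rr$intervals[keep], subject_id = rr$subject_id,
                   condition = rr$condition)
  list(rr = out, removed = sum(!keep))
}

#' Evenly resampled tachogram
#'
#' Interpolates the irregularly sampled tachogram (RR against beat time) with a
#' natural cubic spline and evaluates it on a uniform grid at `fs` Hz, as
#' required before spectral analysis. The grid runs from the first to the last
#' beat time in steps of `1/fs`.
#'
#' @param rr an [rr_series()] with at least 4 beats.
#' @param fs sampling rate in Hz (default 4).
#' @return An object of class `tachogram`: `values` (ms), `fs`, `time`
#'   (grid, s).
#' @export
resample_rr <- function(rr, fs = 4) {
  stopifnot(inherits(rr, "rr_series"))
  n <- length(rr$intervals)
  if (n < 4L) stop_frphrv("cubic-spline resampling needs at least 4 beats")
  t0 <- rr$beat_times[1]
  t1 <- rr$beat_times[n]
  grid <- t0 + seq(0, floor((t1 - t0) * fs)) / fs
  vals <- stats::spline(rr$beat_times, rr$intervals, xout = grid,
                        method = "natural")$y
  structure(list(values = vals, fs = fs, time = grid), class = "tachogram")
}

#' @export
print.tachogram <- function(x, ...) {
  cat(sprintf("Tachogram: %d samples at %g Hz (%.1f s)\n",
              length(x$values), x$fs, diff(range(x$time))))
  invisible(x)
}

#' Write a tachogram as CSV
#'
#' @param tach a [resample_rr()] result.
#' @param path output CSV path with columns `time_s`, `rr_ms`.
#' @return `path`, invisibly.
#' @export
write_tachogram <- function(tach, path) {
  stopifnot(inherits(tach, "tachogram"))
  utils::write.csv(data.frame(time_s = tach$time, rr_ms = tach$values),
                   path, row.names = FALSE)
  invisible(path)
}
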