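# Welch power spectral density of a uniformly sampled series.
# Hann window, `nseg`-sample segments (shortened to the largest power of two
# <= length(x) when the series is short), 50% overlap, per-segment linear
# detrend, one-sided density in units^2/Hz.
welch_psd <- function(x, fs, nseg = 256) {
  n <- length(x)
  nseg <- min(nseg, 2^floor(log2(n)))
  if (nseg < 8) stop_frphrv("series too short for Welch estimation")
  step <- nseg %/% 2L
  starts <- seq(1L, n - nseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nseg) - 1L) / (nseg - 1L))  # Hann
  scale <- fs * sum(w^2)
  nfreq <- nseg %/% 2L + 1L
  acc <- numeric(nfreq)
  tt <- seq_len(nseg)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    seg <- stats::lm.fit(cbind(1, tt), seg)$residuals  # linear detrend
    spec <- abs(stats::fft(seg * w))^2 / scale
    half <- spec[seq_len(nfreq)]
    # one-sided: double everything except DC (and Nyquist when nseg even)
    half[2:(nfreq - 1L)] <- 2 * half[2:(nfreq - 1L)]
    acc <- acc + half
  }
  list(freq = (seq_len(nfreq) - 1L) * fs / nseg, psd = acc / length(starts))
}

band_power <- function(psd, lo, hi) {
  df <- psd$freq[2] - psd$freq[1]
  sum(psd$psd[psd$freq >= lo & psd$freq < hi]) * df
}

#' Time-domain HRV features
#'
#' @param rr an [rr_series()] with at least 2 beats.
#' @return Named numeric vector: `mean_rr` (ms), `sdnn` (ms, sample SD),
#'   `rmssd` (ms, root mean square of successive differences), `pnn50`
#'   (% of successive differences with magnitude > 50 ms), `mean_hr` and
#'   `sd_hr` (bpm, from instantaneous rate 60000/RR).
#' @export
time_domain <- function(rr) {
  stopifnot(inherits(rr, "rr_series"))
  x <- rr$intervals
  if (length(x) < 2L) stop_frphrv("time-domain features need at least 2 beats")
  d <- diff(x)
  hr <- 60000 / x
  c(mean_rr = mean(x),
    sdnn = stats::sd(x),
    rmssd = sqrt(mean(d^2)),
    pnn50 = 100 * mean(abs(d) > 50),
    mean_hr = mean(hr),
    sd_hr = stats::sd(hr))
}

#' Frequency-domain HRV features
#'
#' Welch power spectral density of the mean-removed tachogram, integrated over
#' the conventional bands: VLF 0.003-0.04 Hz, LF 0.04-0.15 Hz, HF 0.15-0.40
#' Hz. Normalized units are taken over LF + HF (VLF excluded), so
#' `lf_nu + hf_nu = 100` identically.
#'
#' @param tach a [resample_rr()] tachogram at 4 Hz with >= 64 samples.
#' @return Named numeric vector: `vlf_power`, `lf_power`, `hf_power`,
#'   `total_power` (ms^2), `lf_nu`, `hf_nu` (%), `lf_hf` (ratio; `Inf` when
#'   HF power is zero).
#' @export
frequency_domain <- function(tach) {
  stopifnot(inherits(tach, "tachogram"))
  if (length(tach$values) < 64L) {
    stop_frphrv("frequency-domain analysis needs >= 64 tachogram samples")
  }
  psd <- welch_psd(tach$values - mean(tach$values), tach$fs)
  vlf <- band_power(psd, 0.003, 0.04)
  lf <- band_power(psd, 0.04, 0.15)
  hf <- band_power(psd, 0.15, 0.40)
  c(vlf_power = vlf, lf_power = lf, hf_power = hf,
    total_power = vlf + lf + hf,
    lf_nu = 100 * lf / (lf + hf),
    hf_nu = 100 * hf / (lf + hf),
    lf_hf = if (hf == 0) Inf else lf / hf)
}

#' Poincare-plot dispersions SD1 and SD2
#'
#' Dispersions of the lagged scatter plot of `(RR_k, RR_(k+1))` about its
#' 45-degree axes: `sd1 = sqrt(var(diff(rr)) / 2)` (short-term, minor axis)
#' and `sd2 = sqrt(2 * var(rr) - var(diff(rr)) / 2)` (long-term, major axis),
#' both with sample variances. A negative radicand for `sd2` is clipped to
#' zero with a warning.
#'
#' @param rr an [rr_series()] with at least 3 beats.
#' @return Named numeric vector `c(sd1, sd2)` in ms.
#' @export
poincare <- function(rr) {
  stopifnot(inherits(rr, "rr_series"))
  x <- rr$intervals
  if (length(x) < 3L) stop_frphrv("Poincare features need at least 3 beats")
  vd <- stats::var(diff(x))
  s2sq <- 2 * stats::var(x) - vd / 2
  if (s2sq < 0) {
    warning("negative SD2 radicand clipped to zero")
    s2sq <- 0
  }
  c(sd1 = sqrt(vd / 2), sd2 = sqrt(s2sq))
}

#' The 15 classic HRV features
#'
#' Convenience wrapper combining [time_domain()], [frequency_domain()] (after
#' [resample_rr()] at `fs`) and [poincare()] into the fixed 15-feature classic
#' panel.
#'
#' @inheritParams time_domain
#' @param fs tachogram resampling rate in Hz.
#' @return Named numeric vector of length 15 in stable order.
#' @export
classic_features <- function(rr, fs = 4) {
  out <- c(time_domain(rr), frequency_domain(resample_rr(rr, fs)), poincare(rr))
  stopifnot(identical(names(out), classic_feature_names))
  out
}

#' @rdname classic_features
#' @format NULL
#' @export
classic_feature_names <- c(
  "mean_rr", "sdnn", "rmssd", "pnn50", "mean_hr", "sd_hr",
  "vlf_power", "lf_power", "hf_power", "total_power", "lf_nu", "hf_nu",
  "lf_hf", "sd1", "sd2"
)
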