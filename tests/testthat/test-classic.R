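test_that("time-domain features match their defining formulas", {
  rr <- rr_series(rep(800, 50))
  td <- time_domain(rr)
  expect_equal(unname(td[c("sdnn", "rmssd", "pnn50")]), c(0, 0, 0))
  expect_equal(unname(td["mean_hr"]), 75)
  td2 <- time_domain(rr_series(c(800, 850)))
  expect_equal(unname(td2["rmssd"]), 50)
  expect_equal(unname(td2["pnn50"]), 0)  # 50 is not > 50
  expect_error(time_domain(rr_series(800)), "2 beats")
})

test_that("time-domain features equal a naive loop recomputation", {
  set.seed(10)
  x <- runif(100, 600, 1100)
  td <- time_domain(rr_series(x))
  n <- length(x)
  m <- sum(x) / n
  sdnn <- sqrt(sum((x - m)^2) / (n - 1))
  ssd <- 0; n50 <- 0
  for (i in 1:(n - 1)) {
    d <- x[i + 1] - x[i]
    ssd <- ssd + d^2
    if (abs(d) > 50) n50 <- n50 + 1
  }
  hr <- 60000 / x
  expect_equal(unname(td), c(m, sdnn, sqrt(ssd / (n - 1)), 100 * n50 / (n - 1),
                             mean(hr), sd(hr)), tolerance = 1e-9)
})

make_tone_tachogram <- function(freq, amp = 30, base = 800, dur = 300, fs = 4) {
  t <- seq(0, dur, by = 1 / fs)
  structure(list(values = base + amp * sin(2 * pi * freq * t), fs = fs,
                 time = t), class = "tachogram")
}

test_that("pure tones land in their spectral bands", {
  lf_tone <- frequency_domain(make_tone_tachogram(0.10))
  expect_gt(lf_tone["lf_nu"], 99)
  hf_tone <- frequency_domain(make_tone_tachogram(0.25))
  expect_gt(hf_tone["hf_nu"], 99)
  expect_lt(hf_tone["lf_hf"], 0.01)
  # oracle: independent periodogram puts the peak at the tone frequency
  tach <- make_tone_tachogram(0.25)
  sp <- stats::spec.pgram(stats::ts(tach$values - mean(tach$values),
                                    frequency = 4), plot = FALSE, taper = 0)
  expect_lt(abs(sp$freq[which.max(sp$spec)] - 0.25), 0.005)
})

test_that("normalized units always sum to 100 and respect the LF/HF ratio", {
  for (s in 1:4) {
    rr <- simulate_rr(spontaneous_params(seed = s, duration_s = 120))
    fd <- frequency_domain(resample_rr(rr))
    expect_equal(unname(fd["lf_nu"] + fd["hf_nu"]), 100, tolerance = 1e-9)
    expect_equal(unname(fd["lf_hf"]), unname(fd["lf_power"] / fd["hf_power"]),
                 tolerance = 1e-12)
    expect_true(all(fd[c("vlf_power", "lf_power", "hf_power")] >= 0))
    expect_equal(unname(fd["total_power"]),
                 unname(sum(fd[c("vlf_power", "lf_power", "hf_power")])),
                 tolerance = 1e-12)
  }
})

test_that("normalized units are invariant to adding a constant", {
  tach <- make_tone_tachogram(0.12)
  f1 <- frequency_domain(tach)
  tach$values <- tach$values + 250
  f2 <- frequency_domain(tach)
  expect_equal(f1[c("lf_nu", "hf_nu", "lf_hf")],
               f2[c("lf_nu", "hf_nu", "lf_hf")], tolerance = 1e-9)
})

test_that("Poincare dispersions match the rotated-cloud oracle", {
  expect_equal(unname(poincare(rr_series(rep(700, 10)))), c(0, 0))
  set.seed(2)
  x <- c(rep(c(800, 900), 20), 800) + rnorm(41, 0, 5)
  sds <- poincare(rr_series(x))
  # oracle: rotate (RR_k, RR_k+1) cloud by 45 degrees and take the SDs
  u <- (x[-1] - x[-length(x)]) / sqrt(2)
  expect_equal(unname(sds["sd1"]), sd(u), tolerance = 1e-6)
  # defining identities on sample variances
  expect_equal(unname(sds["sd1"]^2), var(diff(x)) / 2, tolerance = 1e-9)
  expect_equal(unname(sds["sd2"]^2), 2 * var(x) - var(diff(x)) / 2,
               tolerance = 1e-9)
  expect_error(poincare(rr_series(c(800, 810))), "3 beats")
})

test_that("scaling RR by k scales lengths by k and powers by k^2", {
  rr <- simulate_rr(spontaneous_params(seed = 6, duration_s = 120))
  f1 <- classic_features(rr)
  rr2 <- rr
  rr2$intervals <- rr$intervals * 1.5
  rr2$beat_times <- cumsum(rr2$intervals) / 1000
  f2 <- c(time_domain(rr2), poincare(rr2))
  linear <- c("mean_rr", "sdnn", "rmssd", "sd1", "sd2")
  expect_equal(unname(f2[linear]), unname(1.5 * f1[linear]), tolerance = 1e-9)
  # band powers scale with k^2 when the tachogram values are scaled
  tach <- make_tone_tachogram(0.2)
  p1 <- frequency_domain(tach)
  tach$values <- tach$values * 1.5
  p2 <- frequency_domain(tach)
  bands <- c("vlf_power", "lf_power", "hf_power", "total_power")
  expect_equal(unname(p2[bands]), unname(1.5^2 * p1[bands]), tolerance = 1e-6)
})

test_that("the classic panel has exactly 15 stably named entries", {
  rr <- simulate_rr(spontaneous_params(seed = 7, duration_s = 120))
  f <- classic_features(rr)
  expect_length(f, 15)
  expect_identical(names(f), classic_feature_names)
})
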