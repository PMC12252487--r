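test_that("delay embedding follows its definition", {
  expect_equal(embed_series(c(1, 2, 3, 4), 2, 1),
               matrix(c(1, 2, 3, 2, 3, 4), ncol = 2))
  x <- rnorm(30)
  expect_equal(embed_series(x, 1, 1), matrix(x, ncol = 1))
  expect_equal(nrow(embed_series(x, 4, 3)), 30 - 3 * 3)
  expect_error(embed_series(rnorm(3), 5, 2), "too short")
})

test_that("FCM memberships are a proper fuzzy partition", {
  set.seed(30)
  X <- matrix(rnorm(60), ncol = 2)
  fit <- fcm(X, c = 3, seed = 1)
  expect_true(all(abs(rowSums(fit$membership) - 1) < 1e-9))
  expect_true(all(fit$membership >= 0 & fit$membership <= 1))
})

test_that("the FCM objective is non-increasing over iterations", {
  set.seed(31)
  for (s in 1:3) {
    fit <- fcm(rnorm(80), c = 3, seed = s)
    expect_true(all(diff(fit$objective) <= 1e-8))
    expect_true(fit$converged)
  }
})

test_that("FCM recovers two far-separated blobs", {
  set.seed(32)
  x <- c(rnorm(25, 0, 0.01), rnorm(25, 10, 0.01))
  fit <- fcm(x, c = 2, seed = 5)
  centers <- sort(fit$centers[, 1])
  expect_lt(abs(centers[1] - 0), 0.1)
  expect_lt(abs(centers[2] - 10), 0.1)
  own <- fit$membership[cbind(seq_along(x),
                              apply(fit$membership, 1, which.max))]
  expect_true(all(own > 0.99))
  # memberships agree with blob identity
  lab <- apply(fit$membership, 1, which.max)
  expect_equal(length(unique(lab[1:25])), 1)
  expect_equal(length(unique(lab[26:50])), 1)
  expect_false(lab[1] == lab[26])
})

test_that("FCM is deterministic under a fixed seed and validates c", {
  x <- rnorm(40)
  expect_identical(fcm(x, c = 3, seed = 9), fcm(x, c = 3, seed = 9))
  expect_error(fcm(x, c = 1, seed = 1), "1 < c < N")
  expect_error(fcm(x, c = 40, seed = 1), "1 < c < N")
})

test_that("a point coincident with a centre gets full membership there", {
  # two exact duplicates force zero distances during iteration
  x <- c(rep(0, 10), rep(5, 10))
  fit <- fcm(x, c = 2, seed = 2)
  expect_true(all(abs(rowSums(fit$membership) - 1) < 1e-9))
  expect_true(max(fit$membership[1, ]) > 0.999)
})

test_that("the FRP equals the triple-loop max-min composition", {
  set.seed(33)
  for (rep in 1:4) {
    U <- matrix(rexp(5 * 3), 5, 3)
    U <- U / rowSums(U)
    img <- frp_from_model(as_fcm(U))
    expect_equal(img$pixels, oracle_frp(U))
  }
})

test_that("hand-composed memberships give the expected pixels", {
  U <- rbind(c(1, 0), c(0, 1), c(0.6, 0.4))
  img <- frp_from_model(as_fcm(U))
  expect_equal(img$pixels[1, 2], 0)            # disjoint memberships
  expect_equal(img$pixels[3, 3], 1)            # diagonal overridden
  # identical rows (0.6, 0.4): max(min(.6,.6), min(.4,.4)) = 0.6 off-diagonal
  U2 <- rbind(c(0.6, 0.4), c(0.6, 0.4))
  img2 <- frp_from_model(as_fcm(U2))
  expect_equal(img2$pixels[1, 2], 0.6)
})

test_that("FRP images are symmetric, unit-diagonal and in [0,1]", {
  set.seed(34)
  for (rep in 1:3) {
    img <- frp(rnorm(40), c = 3, seed = rep)
    P <- img$pixels
    expect_identical(P, t(P))
    expect_true(all(diag(P) == 1))
    expect_true(all(P >= 0 & P <= 1))
  }
})

test_that("the FRP is invariant to relabeling clusters", {
  set.seed(35)
  U <- matrix(rexp(8 * 3), 8, 3)
  U <- U / rowSums(U)
  a <- frp_from_model(as_fcm(U))
  b <- frp_from_model(as_fcm(U[, c(3, 1, 2)]))
  expect_equal(a$pixels, b$pixels)
})

test_that("crisp memberships reduce the FRP to a block equivalence relation", {
  lab <- c(1, 2, 1, 3, 2, 2, 3)
  U <- matrix(0, length(lab), 3)
  U[cbind(seq_along(lab), lab)] <- 1
  img <- frp_from_model(as_fcm(U))
  expect_equal(img$pixels, outer(lab, lab, `==`) + 0)
})

test_that("a periodic signal shows recurrence lines at the period lag", {
  # sine wave: 4 Hz, amplitude 5, 1 s at 100 Hz -> period 25 samples
  t <- seq(0, 0.99, by = 0.01)
  x <- 5 * sin(2 * pi * 4 * t)
  img <- frp(x, c = 3, seed = 7)
  P <- img$pixels
  expect_identical(P, t(P))
  expect_true(all(diag(P) == 1))
  lag_mean <- function(l) mean(P[cbind(seq_len(nrow(P) - l), seq_len(nrow(P) - l) + l)])
  period <- 25
  others <- setdiff(5:20, (period - 2):(period + 2))
  expect_gt(lag_mean(period), mean(vapply(others, lag_mean, numeric(1))))
})

test_that("binary recurrence plots threshold pairwise distances", {
  X <- matrix(c(0, 0, 1, 0, 0, 1, 2, 2), ncol = 2, byrow = TRUE)
  rp <- binary_rp(X, eps = 1.2)
  # oracle: pairwise Euclidean distance table
  D <- as.matrix(dist(X))
  expect_equal(rp$pixels, (D <= 1.2) + 0L, ignore_attr = TRUE)
  expect_true(all(binary_rp(X, eps = 10)$pixels == 1))
  rp0 <- binary_rp(rbind(X, X[1, ]), eps = 0)
  expect_equal(rp0$pixels[1, 5], 1L)   # identical states only
  expect_equal(sum(rp0$pixels), 5L + 2L)
  expect_error(binary_rp(X, eps = -1), "non-negative")
})

test_that("rendered FRP files round-trip within 8-bit quantization", {
  img <- frp(sin(seq(0, 6, by = 0.1)), c = 3, seed = 4)
  f <- withr::local_tempfile(fileext = ".png")
  render_frp(img, f)
  back <- read_frp_png(f)
  expect_lt(max(abs(back - img$pixels)), 1 / 255)
  # constant signal: all states share memberships, image is near-uniform
  imgc <- frp(rep(5, 30) + rnorm(30, 0, 1e-9), c = 2, seed = 1)
  off <- imgc$pixels[row(imgc$pixels) != col(imgc$pixels)]
  expect_lt(diff(range(off)), 0.2)
})
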