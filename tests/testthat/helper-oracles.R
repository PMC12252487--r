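# Independent brute-force reference implementations used to pin the fast
# vectorized package code. All are literal loop transcriptions of the
# textbook definitions and share no code with the package internals.

oracle_embed <- function(x, m, tau = 1) {
  n <- length(x) - (m - 1) * tau
  out <- matrix(NA_real_, n, m)
  for (i in seq_len(n)) for (k in seq_len(m)) out[i, k] <- x[i + (k - 1) * tau]
  out
}

oracle_cheb <- function(a, b) max(abs(a - b))

oracle_apen <- function(x, m = 2, r = 0.2) {
  tol <- r * sd(x)
  phi <- function(mm) {
    tm <- oracle_embed(x, mm)
    n <- nrow(tm)
    total <- 0
    for (i in seq_len(n)) {
      cnt <- 0
      for (j in seq_len(n)) if (oracle_cheb(tm[i, ], tm[j, ]) <= tol) cnt <- cnt + 1
      total <- total + log(cnt / n)
    }
    total / n
  }
  phi(m) - phi(m + 1)
}

oracle_sampen <- function(x, m = 2, r = 0.2, tau = 1) {
  tol <- r * sd(x)
  n_t <- length(x) - m * tau     # template count shared by both lengths
  count <- function(mm) {
    tm <- oracle_embed(x, mm, tau)[seq_len(n_t), , drop = FALSE]
    cnt <- 0
    for (i in seq_len(n_t - 1)) for (j in (i + 1):n_t) {
      if (oracle_cheb(tm[i, ], tm[j, ]) <= tol) cnt <- cnt + 1
    }
    cnt
  }
  B <- count(m); A <- count(m + 1)
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

oracle_fuzzen <- function(x, m = 2, tau = 2, r1 = 0.1, r2 = 0.3,
                          hard = FALSE) {
  s <- sd(x)
  mf <- function(d) {
    if (hard || r1 == r2) return(as.numeric(d <= r1 * s))
    if (d <= r1 * s) 1 else if (d >= r2 * s) 0 else (r2 * s - d) / (r2 * s - r1 * s)
  }
  phi <- function(mm) {
    tm <- oracle_embed(x, mm, tau)
    n <- nrow(tm)
    for (i in seq_len(n)) tm[i, ] <- tm[i, ] - mean(tm[i, ])
    tot <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i != j) tot <- tot + mf(oracle_cheb(tm[i, ], tm[j, ]))
    }
    tot / (n * (n - 1))
  }
  log(phi(m) / phi(m + 1))
}

oracle_aape <- function(x, m = 6, tau = 1, a = 0.5) {
  x <- x - mean(x)
  tm <- oracle_embed(x, m, tau)
  acc <- list()
  for (i in seq_len(nrow(tm))) {
    w <- tm[i, ]
    key <- paste(order(w), collapse = ".")
    wt <- a / m * sum(abs(w)) + (1 - a) / (m - 1) * sum(abs(diff(w)))
    acc[[key]] <- (acc[[key]] %||% 0) + wt
  }
  p <- unlist(acc) / sum(unlist(acc))
  p <- p[p > 0]
  -sum(p * log(p))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

oracle_bubble <- function(x, m = 10) {
  swaps <- function(w) {
    cnt <- 0
    n <- length(w)
    repeat {
      done <- TRUE
      for (j in seq_len(n - 1)) {
        if (w[j] > w[j + 1]) {
          w[c(j, j + 1)] <- w[c(j + 1, j)]
          cnt <- cnt + 1
          done <- FALSE
        }
      }
      if (done) break
    }
    cnt
  }
  h2 <- function(mm) {
    tm <- oracle_embed(x, mm)
    cs <- apply(tm, 1, swaps)
    p <- as.numeric(table(cs)) / length(cs)
    -log(sum(p^2))
  }
  (h2(m + 1) - h2(m)) / log((m + 1) / (m - 1))
}

# max-min composition by triple loop
oracle_frp <- function(U) {
  n <- nrow(U); c <- ncol(U)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    best <- 0
    for (k in seq_len(c)) best <- max(best, min(U[i, k], U[j, k]))
    P[i, j] <- best
  }
  diag(P) <- 1
  P
}

# literal transcription of the 19 texture formulas, double loop throughout
oracle_texture <- function(P) {
  L <- nrow(P)
  lg <- function(v) if (v > 0) log(v) else 0
  px <- rowSums(P); py <- colSums(P)
  mu_x <- sum((1:L) * px); mu_y <- sum((1:L) * py)
  sd_x <- sqrt(sum(((1:L) - mu_x)^2 * px))
  sd_y <- sqrt(sum(((1:L) - mu_y)^2 * py))
  psum <- numeric(2 * L); pdiff <- numeric(L)
  for (i in 1:L) for (j in 1:L) {
    psum[i + j] <- psum[i + j] + P[i, j]
    pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + P[i, j]
  }
  f <- c(autocorrelation = 0, contrast = 0, correlation = 0,
         cluster_prominence = 0, cluster_shade = 0, dissimilarity = 0,
         energy = 0, entropy = 0, homogeneity = 0, max_probability = max(P),
         sum_of_squares_variance = 0, sum_average = 0, sum_variance = 0,
         sum_entropy = 0, difference_variance = 0, difference_entropy = 0,
         imc1 = 0, imc2 = 0, inverse_difference = 0)
  HXY <- 0; HXY1 <- 0; HXY2 <- 0
  for (i in 1:L) for (j in 1:L) {
    p <- P[i, j]
    f["autocorrelation"] <- f["autocorrelation"] + i * j * p
    f["contrast"] <- f["contrast"] + (i - j)^2 * p
    f["correlation"] <- f["correlation"] + (i - mu_x) * (j - mu_y) * p
    f["cluster_prominence"] <- f["cluster_prominence"] +
      (i + j - mu_x - mu_y)^4 * p
    f["cluster_shade"] <- f["cluster_shade"] + (i + j - mu_x - mu_y)^3 * p
    f["dissimilarity"] <- f["dissimilarity"] + abs(i - j) * p
    f["energy"] <- f["energy"] + p^2
    HXY <- HXY - p * lg(p)
    f["homogeneity"] <- f["homogeneity"] + p / (1 + (i - j)^2)
    f["sum_of_squares_variance"] <- f["sum_of_squares_variance"] +
      (i - mu_x)^2 * p
    f["inverse_difference"] <- f["inverse_difference"] + p / (1 + abs(i - j))
    HXY1 <- HXY1 - p * lg(px[i] * py[j])
    HXY2 <- HXY2 - px[i] * py[j] * lg(px[i] * py[j])
  }
  f["correlation"] <- f["correlation"] / (sd_x * sd_y)
  f["entropy"] <- HXY
  SA <- sum((2:(2 * L)) * psum[2:(2 * L)])
  f["sum_average"] <- SA
  for (k in 2:(2 * L)) {
    f["sum_variance"] <- f["sum_variance"] + (k - SA)^2 * psum[k]
    f["sum_entropy"] <- f["sum_entropy"] - psum[k] * lg(psum[k])
  }
  DA <- sum((0:(L - 1)) * pdiff)
  for (k in 0:(L - 1)) {
    f["difference_variance"] <- f["difference_variance"] +
      (k - DA)^2 * pdiff[k + 1]
    f["difference_entropy"] <- f["difference_entropy"] -
      pdiff[k + 1] * lg(pdiff[k + 1])
  }
  HX <- -sum(sapply(px, function(v) v * lg(v)))
  HY <- -sum(sapply(py, function(v) v * lg(v)))
  f["imc1"] <- (HXY - HXY1) / max(HX, HY)
  f["imc2"] <- sqrt(1 - exp(-2 * (HXY2 - HXY)))
  f
}

# random normalized GLCM-shaped probability table
random_glcm <- function(L, symmetric = TRUE) {
  P <- matrix(runif(L * L), L, L)
  if (symmetric) P <- P + t(P)
  P / sum(P)
}

as_glcm <- function(P) {
  structure(list(table = P, d = 1L, angle = 0, symmetric = TRUE,
                 normalized = TRUE), class = "glcm")
}

as_fcm <- function(U) {
  structure(list(centers = NULL, membership = U, m = 2, c = ncol(U),
                 tol = 1e-5, n_iter = 0L, converged = TRUE,
                 objective = numeric(0), seed = NULL), class = "fcm")
}
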