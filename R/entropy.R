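# Delay-embedded template matrix: row i = (x_i, x_{i+tau}, ..., x_{i+(m-1)tau}).
embed_templates <- function(x, m, tau = 1L) {
  n <- length(x) - (m - 1L) * tau
  if (n < 1L) stop_frphrv("series too short for embedding dimension ", m)
  idx <- outer(seq_len(n), (seq_len(m) - 1L) * tau, `+`)
  matrix(x[idx], nrow = n)
}

# Pairwise Chebyshev distance between rows of a template matrix.
cheb_dist <- function(tm) {
  n <- nrow(tm)
  d <- matrix(0, n, n)
  for (k in seq_len(ncol(tm))) {
    d <- pmax(d, abs(outer(tm[, k], tm[, k], `-`)))
  }
  d
}

#' Approximate entropy
#'
#' Regularity statistic `ApEn = Phi_m - Phi_(m+1)`, where `Phi_m` is the mean
#' log of self-match-inclusive correlation sums of `m`-sample templates under
#' the Chebyshev distance. The tolerance is `r` times the sample SD of `x`.
#'
#' @param x numeric series.
#' @param m template length (default 2).
#' @param r tolerance as a multiple of `sd(x)` (default 0.2).
#' @return Scalar ApEn; 0 (with a `"degenerate"` attribute) for zero-variance
#'   input.
#' @export
approximate_entropy <- function(x, m = 2L, r = 0.2) {
  if (length(x) < m + 2L) stop_frphrv("series too short for ApEn")
  s <- stats::sd(x)
  if (s == 0) return(structure(0, degenerate = TRUE))
  tol <- r * s
  phi <- function(mm) {
    d <- cheb_dist(embed_templates(x, mm))
    mean(log(rowMeans(d <= tol)))
  }
  phi(m) - phi(m + 1L)
}

#' Sample entropy
#'
#' `SampEn = -log(A / B)` with `B` the number of `m`-template pairs (self
#' matches excluded) within tolerance and `A` the analogous count at `m + 1`
#' (Richman-Moorman counting). Tolerance is `r * sd(x)`; templates are built
#' with delay `tau`.
#'
#' @inheritParams approximate_entropy
#' @param tau embedding delay (default 1).
#' @return Scalar SampEn; 0 for zero-variance input; `NA` (with attribute
#'   `"undefined"`) when no matches exist at either length.
#' @export
sample_entropy <- function(x, m = 2L, r = 0.2, tau = 1L) {
  if (length(x) < (m + 1L) * tau + 1L) stop_frphrv("series too short for SampEn")
  s <- stats::sd(x)
  if (s == 0) return(structure(0, degenerate = TRUE))
  tol <- r * s
  # Richman-Moorman: use the same number of templates (N - m*tau) at both sizes
  n_templates <- length(x) - m * tau
  count_trunc <- function(mm) {
    tm <- embed_templates(x, mm, tau)[seq_len(n_templates), , drop = FALSE]
    d <- cheb_dist(tm)
    (sum(d <= tol) - n_templates) / 2
  }
  B <- count_trunc(m)
  A <- count_trunc(m + 1L)
  if (A == 0 || B == 0) return(structure(NA_real_, undefined = TRUE))
  -log(A / B)
}

# Trapezoidal membership of a distance: 1 on [0, r1], linear down to 0 at r2.
trapezoid_mf <- function(d, r1, r2) {
  if (r2 < r1) stop_frphrv("r2 must be >= r1")
  if (r2 == r1) return(as.numeric(d <= r1))
  pmin(pmax((r2 - d) / (r2 - r1), 0), 1)
}

#' Fuzzy entropy
#'
#' Sample-entropy-style statistic in which the hard tolerance threshold is
#' replaced by a trapezoidal membership of the inter-template Chebyshev
#' distance (full membership up to `r1 * sd(x)`, zero beyond `r2 * sd(x)`),
#' computed on baseline-removed (mean-subtracted) templates. With `r1 == r2`
#' the membership degenerates to the hard threshold.
#'
#' @inheritParams sample_entropy
#' @param r1,r2 trapezoid plateau and zero edges, as multiples of `sd(x)`.
#' @return Scalar FuzzEn; 0 for zero-variance input.
#' @export
fuzzy_entropy <- function(x, m = 2L, tau = 2L, r1 = 0.1, r2 = 0.3) {
  if (length(x) < m * tau + 2L) stop_frphrv("series too short for FuzzEn")
  s <- stats::sd(x)
  if (s == 0) return(structure(0, degenerate = TRUE))
  phi <- function(mm) {
    tm <- embed_templates(x, mm, tau)
    tm <- tm - rowMeans(tm)          # remove local baseline
    d <- cheb_dist(tm)
    mu <- trapezoid_mf(d, r1 * s, r2 * s)
    n <- nrow(tm)
    (sum(mu) - n) / (n * (n - 1))    # mean over ordered pairs, self excluded
  }
  p_m <- phi(m)
  p_m1 <- phi(m + 1L)
  if (p_m1 == 0 || p_m == 0) return(structure(NA_real_, undefined = TRUE))
  log(p_m / p_m1)
}

#' Amplitude-aware permutation entropy
#'
#' Permutation entropy in which each ordinal pattern contributes a weight that
#' mixes the window's mean absolute amplitude and mean absolute successive
#' difference through the coefficient `a`:
#' `w = (a/m) * sum(|x_k|) + ((1-a)/(m-1)) * sum(|x_k - x_(k-1)|)`.
#' Pattern weights are normalized to probabilities and Shannon entropy (nats)
#' is returned; for white noise it approaches `log(factorial(m))` from below.
#' The series is mean-centred before weighting so the amplitude term (and
#' hence the statistic) is invariant to additive shifts, like the other four
#' entropy measures in the panel.
#'
#' @inheritParams sample_entropy
#' @param m pattern length (default 6).
#' @param a amplitude/deviation mixing coefficient in [0, 1] (default 0.5).
#' @return Scalar entropy in nats; 0 when a single pattern occurs.
#' @export
aape <- function(x, m = 6L, tau = 1L, a = 0.5) {
  if (a < 0 || a > 1) stop_frphrv("a must lie in [0, 1]")
  x <- x - mean(x)
  tm <- embed_templates(x, m, tau)
  n <- nrow(tm)
  patterns <- apply(tm, 1L, function(w) paste(order(w), collapse = "."))
  weights <- apply(tm, 1L, function(w) {
    a / m * sum(abs(w)) + (1 - a) / (m - 1) * sum(abs(diff(w)))
  })
  tot <- tapply(weights, patterns, sum)
  if (sum(tot) == 0) return(structure(0, degenerate = TRUE))
  p <- tot / sum(tot)
  p <- p[p > 0]
  -sum(p * log(p))
}

# Number of swaps bubble sort needs to order w ascending (= inversion count).
bubble_swaps <- function(w) {
  n <- length(w)
  swaps <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq_len(n - i)) {
      if (w[j] > w[j + 1L]) {
        tmp <- w[j]; w[j] <- w[j + 1L]; w[j + 1L] <- tmp
        swaps <- swaps + 1L
      }
    }
  }
  swaps
}

# Renyi-2 entropy of the swap-count distribution at embedding mm.
renyi2_swaps <- function(x, mm) {
  tm <- embed_templates(x, mm)
  counts <- apply(tm, 1L, bubble_swaps)
  p <- tabulate(counts + 1L, nbins = mm * (mm - 1L) %/% 2L + 1L) / nrow(tm)
  -log(sum(p^2))
}

#' Bubble entropy
#'
#' Renyi-2 entropy of the distribution of bubble-sort swap counts over sliding
#' windows, differenced between embeddings `m + 1` and `m` and normalized by
#' `log((m + 1) / (m - 1))` (Manis-style normalization). Monotone series need
#' no swaps at either embedding, giving 0; the statistic is rank-based and so
#' invariant to adding a constant.
#'
#' @inheritParams sample_entropy
#' @param m embedding dimension (default 10).
#' @return Scalar bubble entropy.
#' @export
bubble_entropy <- function(x, m = 10L) {
  if (length(x) < m + 2L) stop_frphrv("series too short for bubble entropy")
  (renyi2_swaps(x, m + 1L) - renyi2_swaps(x, m)) / log((m + 1) / (m - 1))
}

#' Entropy hyperparameter block
#'
#' Default hyperparameters of the five entropy measures: ApEn m=2, r=0.2;
#' SampEn m=2, r=0.2, tau=1; FuzzEn m=2, trapezoidal membership, tau=2;
#' amplitude-aware permutation entropy m=6, tau=1, a=0.5; bubble entropy
#' m=10. The trapezoid corners (r1=0.1, r2=0.3, in SD units) are this
#' package's documented choice, as only the membership shape is standard.
#'
#' @param ... overrides of any listed element.
#' @return A named list of hyperparameters.
#' @export
entropy_config <- function(...) {
  cfg <- list(apen_m = 2L, apen_r = 0.2,
              sampen_m = 2L, sampen_r = 0.2, sampen_tau = 1L,
              fuzzen_m = 2L, fuzzen_tau = 2L, fuzzen_r1 = 0.1, fuzzen_r2 = 0.3,
              aape_m = 6L, aape_tau = 1L, aape_a = 0.5,
              bubble_m = 10L)
  utils::modifyList(cfg, list(...))
}

#' The five entropy features of a series
#'
#' @param x numeric series (typically RR intervals in ms).
#' @param config an [entropy_config()] list.
#' @return Named numeric vector `c(apen, sampen, fuzzen, aape, bubble)`.
#' @export
entropy_features <- function(x, config = entropy_config()) {
  c(apen = as.numeric(approximate_entropy(x, config$apen_m, config$apen_r)),
    sampen = as.numeric(sample_entropy(x, config$sampen_m, config$sampen_r,
                                       config$sampen_tau)),
    fuzzen = as.numeric(fuzzy_entropy(x, config$fuzzen_m, config$fuzzen_tau,
                                      config$fuzzen_r1, config$fuzzen_r2)),
    aape = as.numeric(aape(x, config$aape_m, config$aape_tau, config$aape_a)),
    bubble = as.numeric(bubble_entropy(x, config$bubble_m)))
}

#' @rdname entropy_features
#' @format NULL
#' @export
entropy_feature_names <- c("apen", "sampen", "fuzzen", "aape", "bubble")
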