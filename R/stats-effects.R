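#' Kolmogorov-Smirnov normality screen
#'
#' One-sample KS test of `x` against a normal with the sample mean and SD.
#' Because the parameters are estimated from the same data the p-value is
#' conservative (no Lilliefors correction); the screen is reported only and
#' never gates the nonparametric pipeline.
#'
#' @param x numeric sample, n >= 5.
#' @return List with `statistic`, `p`, and `testable` (FALSE for
#'   zero-variance input, in which case the other fields are `NA`).
#' @export
ks_normality <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 5L) stop_frphrv("KS screen needs at least 5 observations")
  if (stats::sd(x) == 0) {
    return(list(statistic = NA_real_, p = NA_real_, testable = FALSE))
  }
  kt <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
  list(statistic = unname(kt$statistic), p = kt$p.value, testable = TRUE)
}

# Exact two-sided signed-rank p-value by enumerating all 2^n sign assignments
# of the observed |difference| ranks.
wilcoxon_exact_p <- function(W, ranks) {
  n <- length(ranks)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- as.vector(signs %*% ranks)
  mean_W <- n * (n + 1) / 4
  # two-sided: assignments at least as extreme (in |W - E[W]|) as observed
  mean(abs(Ws - mean_W) >= abs(W - mean_W) - 1e-12)
}

#' Wilcoxon signed-rank test for paired features
#'
#' Paired two-sided test on `values_a - values_b`. Zero differences are
#' dropped; ties among the absolute differences are mid-ranked. The statistic
#' `W` is the sum of the ranks of positive differences. The p-value is exact
#' (full enumeration of sign assignments) when the effective sample size is
#' at most `exact_max`, otherwise a tie-corrected normal approximation is
#' used.
#'
#' @param values_a,values_b paired samples aligned by subject; pairs with a
#'   missing value in either member are excluded.
#' @param exact_max largest effective n for the exact enumeration (default 12).
#' @return List of class `wilcoxon_test`: `W`, `p`, `rbc` (rank-biserial
#'   correlation), `n_effective`, `significant` (p < 0.05), `method`.
#' @export
wilcoxon_signed_rank <- function(values_a, values_b, exact_max = 12L) {
  if (length(values_a) != length(values_b)) {
    stop_frphrv("paired samples must have equal length")
  }
  ok <- !(is.na(values_a) | is.na(values_b))
  d <- values_a[ok] - values_b[ok]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop_frphrv("all paired differences are zero: test undefined")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_max) {
    p <- wilcoxon_exact_p(W, r)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    # continuity-corrected z with an Edgeworth (fourth-cumulant) refinement:
    # W is a sum of independent scaled Bernoulli(1/2) terms, so kappa4 =
    # -(1/8) * sum(rank^4); the correction keeps the approximation within
    # ~0.01 of the exact tail down to n around 12
    z <- (abs(W - mu) - 0.5) / sqrt(sigma2)
    gamma2 <- -(sum(r^4) / 8) / sigma2^2
    tail <- stats::pnorm(-z) + gamma2 / 24 * (z^3 - 3 * z) * stats::dnorm(z)
    p <- 2 * max(tail, 0)
    method <- "normal approximation"
  }
  p <- min(max(p, .Machine$double.xmin), 1)
  structure(list(W = W, p = p, rbc = rank_biserial(values_a, values_b),
                 n_effective = n, significant = p < 0.05, method = method),
            class = "wilcoxon_test")
}

#' @export
print.wilcoxon_test <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank (%s): W = %g, n = %d, p = %.4g%s, RBC = %.3f\n",
              x$method, x$W, x$n_effective, x$p,
              if (x$significant) " *" else "", x$rbc))
  invisible(x)
}

#' Rank-biserial correlation for paired samples
#'
#' Kerby's simple-difference effect size: the difference between the rank-sum
#' proportions of favorable (positive) and unfavorable (negative) differences,
#' `rbc = (sum of positive-difference ranks - sum of negative-difference
#' ranks) / total rank sum`, in [-1, +1]. Zero differences are dropped; pairs
#' with missing values are excluded.
#'
#' @inheritParams wilcoxon_signed_rank
#' @return Scalar in [-1, 1]; `NA` when all differences are zero.
#' @export
rank_biserial <- function(values_a, values_b) {
  ok <- !(is.na(values_a) | is.na(values_b))
  d <- values_a[ok] - values_b[ok]
  d <- d[d != 0]
  if (length(d) == 0L) return(NA_real_)
  r <- rank(abs(d))
  (sum(r[d > 0]) - sum(r[d < 0])) / sum(r)
}

#' Per-feature paired statistics table
#'
#' Runs the KS screen, Wilcoxon signed-rank test and rank-biserial effect
#' size for every feature of a paired feature table, comparing
#' `condition_b` (e.g. slow-paced) against `condition_a` (spontaneous);
#' positive effect sizes mean the feature is larger under `condition_b`.
#'
#' @param table a [cohort_features()] feature table with paired conditions.
#' @param condition_a,condition_b condition labels defining the pairing
#'   (differences are `condition_b - condition_a`).
#' @return A data.frame with one row per feature: `feature`, `ks_p`, `W`,
#'   `p`, `rbc`, `n_effective`, `significant`.
#' @export
paired_feature_stats <- function(table, condition_a = "spontaneous",
                                 condition_b = "slow_paced") {
  tm <- table_matrix(table)
  a_idx <- which(tm$condition == condition_a)
  b_idx <- which(tm$condition == condition_b)
  a_idx <- a_idx[match(tm$subject_id[b_idx], tm$subject_id[a_idx])]
  stopifnot(length(a_idx) == length(b_idx), !anyNA(a_idx))
  rows <- lapply(colnames(tm$x), function(f) {
    b <- tm$x[b_idx, f]; a <- tm$x[a_idx, f]
    ks <- tryCatch(ks_normality(c(a, b))$p, error = function(e) NA_real_)
    wt <- wilcoxon_signed_rank(b, a)
    data.frame(feature = f, ks_p = ks, W = wt$W, p = wt$p, rbc = wt$rbc,
               n_effective = wt$n_effective, significant = wt$significant,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
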