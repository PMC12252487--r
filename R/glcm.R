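#' Quantize an FRP image to discrete grey levels
#'
#' Uniform binning of [0, 1] into `levels` equal-width bins: a pixel value `v`
#' maps to level `floor(v * levels) + 1`, with `v = 1` assigned to the top
#' bin. The membership matrix is quantized directly (not the rendered 8-bit
#' file), avoiding double quantization.
#'
#' @param image an [frp()] object or a numeric matrix with values in [0, 1].
#' @param levels number of grey levels, >= 2 (default 8).
#' @return Integer matrix of levels in `1..levels`.
#' @export
quantize <- function(image, levels = 8L) {
  if (levels < 2L) stop_frphrv("levels must be >= 2")
  px <- if (inherits(image, "frp")) image$pixels else image
  if (any(px < 0 | px > 1)) stop_frphrv("pixel values must lie in [0, 1]")
  q <- pmin(floor(px * levels) + 1L, levels)
  storage.mode(q) <- "integer"
  q
}

#' Grey-level co-occurrence matrix
#'
#' Counts ordered pairs of grey levels at a fixed pixel offset (distance `d`
#' along `angle`), optionally accumulated symmetrically (pair + transpose) and
#' normalized to a joint probability table. The pipeline default is the
#' horizontal offset `d = 1` with symmetric, normalized accumulation.
#'
#' @param q integer level matrix from [quantize()].
#' @param levels number of levels (defaults to `max(q)` if not 8-bounded).
#' @param d offset distance in pixels (default 1).
#' @param angle one of 0, 45, 90, 135 degrees (default 0, horizontal).
#' @param symmetric add the transposed counts (default `TRUE`).
#' @param normalize divide by the total count (default `TRUE`).
#' @return An object of class `glcm`: `table` (levels x levels), `d`, `angle`,
#'   `symmetric`, `normalized`.
#' @export
glcm <- function(q, levels = max(q), d = 1L, angle = 0,
                 symmetric = TRUE, normalize = TRUE) {
  if (!angle %in% c(0, 45, 90, 135)) {
    stop_frphrv("angle must be one of 0, 45, 90, 135")
  }
  nr <- nrow(q); nc <- ncol(q)
  # offset (row, col) for each orientation; rows grow downward
  off <- switch(as.character(angle),
                "0" = c(0L, d), "45" = c(-d, d), "90" = c(-d, 0L),
                "135" = c(-d, -d))
  ri <- seq_len(nr); ci <- seq_len(nc)
  r1 <- ri[ri + off[1] >= 1L & ri + off[1] <= nr]
  c1 <- ci[ci + off[2] >= 1L & ci + off[2] <= nc]
  if (length(r1) == 0L || length(c1) == 0L) {
    stop_frphrv("image too small for the requested offset")
  }
  a <- q[r1, c1, drop = FALSE]
  b <- q[r1 + off[1], c1 + off[2], drop = FALSE]
  G <- matrix(0, levels, levels)
  tab <- table(factor(a, levels = seq_len(levels)),
               factor(b, levels = seq_len(levels)))
  G <- G + as.matrix(tab)
  if (symmetric) G <- G + t(G)
  if (normalize) G <- G / sum(G)
  dimnames(G) <- NULL
  structure(list(table = G, d = d, angle = angle, symmetric = symmetric,
                 normalized = normalize),
            class = "glcm")
}

#' @export
print.glcm <- function(x, ...) {
  cat(sprintf("GLCM: %d levels, d = %d, angle = %g deg%s%s\n",
              nrow(x$table), x$d, x$angle,
              if (x$symmetric) ", symmetric" else "",
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

# 0 * log(0) = 0 convention used by every entropy-bearing texture feature.
xlogx <- function(p) ifelse(p > 0, p * log(p), 0)

#' The 19 Haralick-style GLCM texture features
#'
#' Computes the canonical texture statistics of a normalized co-occurrence
#' table `p(i, j)` over levels `i, j = 1..L`: autocorrelation, contrast,
#' correlation, cluster prominence, cluster shade, dissimilarity, energy,
#' entropy, homogeneity, maximum probability, sum-of-squares variance, sum
#' average, sum variance, sum entropy, difference variance, difference
#' entropy, the two information measures of correlation, and inverse
#' difference. All logarithms are natural with the `0 log 0 = 0` convention.
#' Degenerate marginals make the information measures undefined; they are
#' returned as `NA`.
#'
#' @param g a normalized [glcm()].
#' @return Named numeric vector of exactly 19 features.
#' @export
texture_features <- function(g) {
  stopifnot(inherits(g, "glcm"))
  if (!g$normalized) stop_frphrv("texture features require a normalized GLCM")
  p <- g$table
  L <- nrow(p)
  i <- row(p); j <- col(p)
  px <- rowSums(p); py <- colSums(p)
  mu_x <- sum(seq_len(L) * px); mu_y <- sum(seq_len(L) * py)
  sd_x <- sqrt(sum((seq_len(L) - mu_x)^2 * px))
  sd_y <- sqrt(sum((seq_len(L) - mu_y)^2 * py))

  # marginal distributions of i + j (2..2L) and |i - j| (0..L-1)
  p_sum <- vapply(2:(2 * L), function(k) sum(p[i + j == k]), numeric(1))
  p_diff <- vapply(0:(L - 1), function(k) sum(p[abs(i - j) == k]), numeric(1))
  ks <- 2:(2 * L); kd <- 0:(L - 1)
  sum_avg <- sum(ks * p_sum)
  diff_avg <- sum(kd * p_diff)

  HXY <- -sum(xlogx(p))
  HX <- -sum(xlogx(px)); HY <- -sum(xlogx(py))
  pxy <- outer(px, py)
  HXY1 <- -sum(p * ifelse(pxy > 0, log(pxy), 0))
  HXY2 <- -sum(xlogx(pxy))
  denom <- max(HX, HY)
  imc1 <- if (denom == 0) NA_real_ else (HXY - HXY1) / denom
  imc2_arg <- 1 - exp(-2 * (HXY2 - HXY))
  imc2 <- if (imc2_arg < 0) NA_real_ else sqrt(imc2_arg)

  corr <- if (sd_x == 0 || sd_y == 0) NA_real_ else
    sum((i - mu_x) * (j - mu_y) * p) / (sd_x * sd_y)

  c(autocorrelation = sum(i * j * p),
    contrast = sum((i - j)^2 * p),
    correlation = corr,
    cluster_prominence = sum((i + j - mu_x - mu_y)^4 * p),
    cluster_shade = sum((i + j - mu_x - mu_y)^3 * p),
    dissimilarity = sum(abs(i - j) * p),
    energy = sum(p^2),
    entropy = HXY,
    homogeneity = sum(p / (1 + (i - j)^2)),
    max_probability = max(p),
    sum_of_squares_variance = sum((i - mu_x)^2 * p),
    sum_average = sum_avg,
    sum_variance = sum((ks - sum_avg)^2 * p_sum),
    sum_entropy = -sum(xlogx(p_sum)),
    difference_variance = sum((kd - diff_avg)^2 * p_diff),
    difference_entropy = -sum(xlogx(p_diff)),
    imc1 = imc1,
    imc2 = imc2,
    inverse_difference = sum(p / (1 + abs(i - j))))
}

#' @rdname texture_features
#' @format NULL
#' @export
texture_feature_names <- c(
  "autocorrelation", "contrast", "correlation", "cluster_prominence",
  "cluster_shade", "dissimilarity", "energy", "entropy", "homogeneity",
  "max_probability", "sum_of_squares_variance", "sum_average", "sum_variance",
  "sum_entropy", "difference_variance", "difference_entropy", "imc1", "imc2",
  "inverse_difference"
)
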