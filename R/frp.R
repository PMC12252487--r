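#' Fuzzy recurrence plot from a fuzzy cluster model
#'
#' Builds the N x N fuzzy recurrence image from FCM memberships by max-min
#' fuzzy-relation composition: `pixel(i, j) = max_k min(U[i,k], U[j,k])` for
#' `i != j`, with the diagonal set to 1 by the reflexivity property. The
#' result is symmetric with all values in [0, 1].
#'
#' @param model an [fcm()] model.
#' @param subject_id,condition optional provenance labels stored on the image.
#' @return An object of class `frp`: `pixels` (N x N matrix) plus metadata
#'   (`c`, `m`, `subject_id`, `condition`).
#' @export
frp_from_model <- function(model, subject_id = NA_character_,
                           condition = NA_character_) {
  stopifnot(inherits(model, "fcm"))
  U <- model$membership
  n <- nrow(U)
  P <- matrix(0, n, n)
  for (k in seq_len(ncol(U))) {
    P <- pmax(P, outer(U[, k], U[, k], pmin))
  }
  diag(P) <- 1
  structure(list(pixels = P, c = model$c, m = model$m,
                 subject_id = subject_id, condition = condition),
            class = "frp")
}

#' Fuzzy recurrence plot of a time series
#'
#' One-call interface: delay-embeds the series ([embed_series()]), fits fuzzy
#' C-means ([fcm()]) and composes the fuzzy recurrence image
#' ([frp_from_model()]). With the defaults (`dim = 1`, `tau = 1`) each sample
#' is a scalar state, the natural choice for RR tachograms.
#'
#' @param x numeric series (e.g. RR intervals in ms).
#' @param c number of fuzzy clusters (default 3).
#' @param m fuzzifier (default 2).
#' @param dim,tau embedding dimension and delay.
#' @param seed RNG seed for the FCM initialization.
#' @param ... further arguments to [fcm()].
#' @inheritParams frp_from_model
#' @return An `frp` object; the fitted `fcm` model is attached as
#'   `attr(, "model")`.
#' @examples
#' x <- sin(2 * pi * 4 * seq(0, 1, by = 0.01)) * 5
#' p <- frp(x, c = 3, seed = 1)
#' @export
frp <- function(x, c = 3, m = 2, dim = 1L, tau = 1L, seed = NULL,
                subject_id = NA_character_, condition = NA_character_, ...) {
  X <- embed_series(x, dim, tau)
  model <- fcm(X, c = c, m = m, seed = seed, ...)
  out <- frp_from_model(model, subject_id = subject_id, condition = condition)
  attr(out, "model") <- model
  out
}

#' @export
print.frp <- function(x, ...) {
  cat(sprintf("Fuzzy recurrence plot: %d x %d pixels (c = %d, m = %g)\n",
              nrow(x$pixels), ncol(x$pixels), x$c, x$m))
  invisible(x)
}

#' @export
as.matrix.frp <- function(x, ...) x$pixels

#' @export
#' @param col greyscale palette; high membership plots dark by default
#'   (recurrent points are dark, as in recurrence-plot convention).
#' @rdname frp
plot.frp <- function(x, col = grey(seq(1, 0, length.out = 256)), ...) {
  n <- nrow(x$pixels)
  graphics::image(seq_len(n), seq_len(n), t(x$pixels[n:1, , drop = FALSE]),
                  col = col, zlim = c(0, 1), asp = 1, axes = FALSE,
                  xlab = "", ylab = "", ...)
  invisible(x)
}

#' Binary recurrence plot
#'
#' Classical thresholded recurrence matrix: `pixel(i, j) = 1` iff the
#' Euclidean distance between states `i` and `j` is at most `eps`
#' (Heaviside convention `H(0) = 1`).
#'
#' @param X state matrix from [embed_series()] (or numeric vector).
#' @param eps recurrence threshold, >= 0, in signal units.
#' @return An object of class `binary_rp`: `pixels` (0/1 matrix), `eps`.
#' @export
binary_rp <- function(X, eps) {
  if (eps < 0) stop_frphrv("eps must be non-negative")
  if (is.vector(X)) X <- matrix(as.numeric(X), ncol = 1L)
  d2 <- pmax(outer(rowSums(X^2), rowSums(X^2), `+`) - 2 * X %*% t(X), 0)
  structure(list(pixels = (sqrt(d2) <= eps) + 0L, eps = eps),
            class = "binary_rp")
}

#' @export
print.binary_rp <- function(x, ...) {
  cat(sprintf("Binary recurrence plot: %d x %d, eps = %g, density %.3f\n",
              nrow(x$pixels), ncol(x$pixels), x$eps, mean(x$pixels)))
  invisible(x)
}

#' Render a fuzzy recurrence plot to a greyscale PNG
#'
#' Writes an 8-bit lossless greyscale image. By default recurrent (high
#' membership) pixels are dark: stored intensity is `1 - membership`;
#' `invert = FALSE` stores the membership directly.
#'
#' @param image an [frp()] object.
#' @param path output PNG path.
#' @param invert store `1 - membership` (dark = recurrent, default) rather
#'   than the raw membership.
#' @return `path`, invisibly.
#' @export
render_frp <- function(image, path, invert = TRUE) {
  stopifnot(inherits(image, "frp"))
  px <- if (invert) 1 - image$pixels else image$pixels
  png::writePNG(px, path)
  invisible(path)
}

#' Re-read a rendered FRP image
#'
#' @param path PNG written by [render_frp()].
#' @param invert must match the `invert` used when rendering.
#' @return Numeric matrix of memberships in [0, 1] (quantized to 8 bits).
#' @export
read_frp_png <- function(path, invert = TRUE) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1L]
  if (invert) 1 - px else px
}
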