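#' Delay embedding of a series into a state matrix
#'
#' Row `k` of the result is `(x_k, x_(k+tau), ..., x_(k+(dim-1)tau))`. With
#' `dim = 1` the series itself is returned as a one-column matrix (the default
#' used for RR tachograms, where each beat is a scalar state).
#'
#' @param x numeric series.
#' @param dim embedding dimension, >= 1.
#' @param tau embedding delay, >= 1.
#' @return Numeric matrix with `length(x) - (dim - 1) * tau` rows.
#' @export
embed_series <- function(x, dim = 1L, tau = 1L) {
  if (dim < 1L || tau < 1L) stop_frphrv("dim and tau must be >= 1")
  embed_templates(as.numeric(x), as.integer(dim), as.integer(tau))
}

#' Fuzzy C-means clustering
#'
#' Minimizes the fuzzified within-cluster scatter
#' `J(U, Z) = sum_i sum_j u_ij^m d(x_i, z_j)^2` by alternating updates of the
#' membership matrix `U` (rows sum to one) and the cluster centres `Z`, from a
#' seeded random (Dirichlet-per-row) initialization of `U`. Iteration stops
#' when `max |U_t - U_(t+1)| <= tol` or at `max_iter`. A data point coincident
#' with a centre receives full membership in the zero-distance centre(s).
#'
#' @param X numeric matrix of states (rows) by coordinates (columns), or a
#'   numeric vector treated as one-column.
#' @param c number of clusters, `1 < c < nrow(X)`.
#' @param m fuzzifier (fuzzy weighting exponent), > 1; default 2.
#' @param tol convergence level on the membership max-norm; default 1e-5.
#' @param max_iter iteration cap; default 200.
#' @param seed RNG seed for the initialization (reproducibility).
#' @return An object of class `fcm`: `centers` (c x D), `membership` (N x c),
#'   `m`, `c`, `tol`, `n_iter`, `converged`, `objective` (J trace), `seed`.
#' @export
fcm <- function(X, c, m = 2, tol = 1e-5, max_iter = 200L, seed = NULL) {
  if (is.vector(X)) X <- matrix(as.numeric(X), ncol = 1L)
  n <- nrow(X)
  if (!(c > 1 && c < n)) stop_frphrv("cluster count must satisfy 1 < c < N")
  if (m <= 1) stop_frphrv("fuzzifier m must exceed 1")
  U <- with_seed(seed, {
    u <- matrix(stats::rexp(n * c), n, c)   # Dirichlet(1,...,1) rows
    u / rowSums(u)
  })
  sq_dist <- function(Z) {
    # squared Euclidean distance between every state and every centre
    d <- outer(rowSums(X^2), rowSums(Z^2), `+`) - 2 * X %*% t(Z)
    pmax(d, 0)
  }
  update_U <- function(d2) {
    zero <- d2 < .Machine$double.eps
    expo <- 1 / (m - 1)
    Unew <- 1 / (d2^expo * rowSums((1 / d2)^expo))
    hit <- rowSums(zero) > 0
    if (any(hit)) {
      Unew[hit, ] <- 0
      Unew[hit, ] <- zero[hit, , drop = FALSE] / rowSums(zero[hit, , drop = FALSE])
    }
    Unew
  }
  J <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Um <- U^m
    Z <- (t(Um) %*% X) / colSums(Um)
    d2 <- sq_dist(Z)
    Unew <- update_U(d2)
    J <- c(J, sum(Unew^m * d2))
    delta <- max(abs(Unew - U))
    U <- Unew
    if (delta <= tol) { converged <- TRUE; break }
  }
  if (!converged) warning("FCM did not converge within max_iter iterations")
  structure(list(centers = Z, membership = U, m = m, c = c, tol = tol,
                 n_iter = it, converged = converged, objective = J,
                 seed = seed),
            class = "fcm")
}

#' @export
print.fcm <- function(x, ...) {
  cat(sprintf("Fuzzy C-means: %d clusters, fuzzifier %g, %d states\n",
              x$c, x$m, nrow(x$membership)))
  cat(sprintf("  %s after %d iterations (J = %.6g)\n",
              if (x$converged) "converged" else "NOT converged",
              x$n_iter, x$objective[length(x$objective)]))
  invisible(x)
}

#' @export
#' @rdname fcm
#' @param object an `fcm` model.
#' @param newdata states to score; defaults to refusing (memberships of the
#'   training states live in `object$membership`).
#' @param ... unused.
predict.fcm <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$membership)
  if (is.vector(newdata)) newdata <- matrix(as.numeric(newdata), ncol = 1L)
  Z <- object$centers
  d2 <- pmax(outer(rowSums(newdata^2), rowSums(Z^2), `+`) -
               2 * newdata %*% t(Z), 0)
  expo <- 1 / (object$m - 1)
  U <- 1 / (d2^expo * rowSums((1 / d2)^expo))
  zero <- d2 < .Machine$double.eps
  hit <- rowSums(zero) > 0
  if (any(hit)) {
    U[hit, ] <- 0
    U[hit, ] <- zero[hit, , drop = FALSE] / rowSums(zero[hit, , drop = FALSE])
  }
  U
}
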