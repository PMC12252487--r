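#' Z-score standardization of a feature table
#'
#' Centres each feature column to mean 0 and scales to sample SD 1. Constant
#' columns (z undefined) are dropped with a warning. The transform parameters
#' are stored so held-out data can be standardized identically.
#'
#' @param table a feature table (data.frame with optional `subject_id` /
#'   `condition` metadata columns).
#' @param params optional stored transform from a previous call
#'   (`attr(, "zscore_params")`); when supplied it is applied instead of
#'   refitted.
#' @return The standardized table, with `attr(, "zscore_params")` =
#'   list(center, scale).
#' @export
zscore <- function(table, params = NULL) {
  tm <- table_matrix(table)
  if (nrow(tm$x) < 2L) stop_frphrv("z-scoring needs at least 2 rows")
  if (is.null(params)) {
    center <- colMeans(tm$x)
    scale <- apply(tm$x, 2L, stats::sd)
    const <- scale == 0 | !is.finite(scale)
    if (any(const)) {
      warning("dropping constant column(s): ",
              paste(colnames(tm$x)[const], collapse = ", "))
    }
    params <- list(center = center[!const], scale = scale[!const])
  }
  keep <- names(params$center)
  z <- sweep(sweep(tm$x[, keep, drop = FALSE], 2L, params$center), 2L,
             params$scale, `/`)
  meta <- intersect(c("subject_id", "condition"), names(table))
  out <- cbind(table[, meta, drop = FALSE], as.data.frame(z))
  class(out) <- class(table)
  attr(out, "zscore_params") <- params
  out
}

#' Fisher discriminant ratio ranking
#'
#' Scores every feature by the two-class Fisher discriminant ratio
#' `FDR = (mu1 - mu2)^2 / (sigma1^2 + sigma2^2)` (sample means and
#' variances), sorts descending, and flags the survivors with FDR strictly
#' above `threshold`. Ties in FDR are broken alphabetically by feature name.
#' A feature with both class variances zero but different means receives
#' `Inf` and ranks first; equal means with zero variance give 0.
#'
#' @param table feature table.
#' @param labels binary class labels (factor or character), one per row;
#'   defaults to the table's `condition` column.
#' @param threshold survivor cut (default 0.95, strict inequality).
#' @return A data.frame ranked by decreasing FDR: `feature`, `fdr`, `mu1`,
#'   `mu2`, `var1`, `var2`, `survivor`.
#' @export
fdr_rank <- function(table, labels = NULL, threshold = 0.95) {
  tm <- table_matrix(table)
  labels <- labels %||% tm$condition
  cls <- sort(unique(as.character(labels)))
  if (length(cls) != 2L) stop_frphrv("FDR ranking needs exactly 2 classes")
  g1 <- labels == cls[1]; g2 <- labels == cls[2]
  if (sum(g1) < 2L || sum(g2) < 2L) {
    stop_frphrv("both classes need at least 2 instances")
  }
  mu1 <- colMeans(tm$x[g1, , drop = FALSE])
  mu2 <- colMeans(tm$x[g2, , drop = FALSE])
  v1 <- apply(tm$x[g1, , drop = FALSE], 2L, stats::var)
  v2 <- apply(tm$x[g2, , drop = FALSE], 2L, stats::var)
  fdr <- ifelse(v1 + v2 == 0,
                ifelse(mu1 == mu2, 0, Inf),
                (mu1 - mu2)^2 / (v1 + v2))
  out <- data.frame(feature = colnames(tm$x), fdr = fdr, mu1 = mu1, mu2 = mu2,
                    var1 = v1, var2 = v2, row.names = NULL,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$fdr, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  out$survivor <- out$fdr > threshold
  out
}

#' Correlation-redundancy filter
#'
#' Walks the FDR survivors in descending-FDR order and accepts a feature only
#' if its absolute Pearson correlation with every already-accepted feature is
#' at most `threshold`. Rejections are logged with the blocking pair.
#'
#' @param table feature table (correlations are computed on its columns; use
#'   the z-scored table for the pipeline convention).
#' @param ranking a [fdr_rank()] result (only survivors are considered).
#' @param threshold absolute-correlation rejection cut (default 0.9).
#' @return List: `accepted` (character vector in acceptance order), `removed`
#'   (data.frame feature/blocked_by/correlation).
#' @export
correlation_filter <- function(table, ranking, threshold = 0.9) {
  tm <- table_matrix(table)
  cand <- ranking$feature[ranking$survivor]
  if (length(cand) == 0L) stop_frphrv("no FDR survivors to filter")
  accepted <- character(0)
  removed <- data.frame(feature = character(0), blocked_by = character(0),
                        correlation = numeric(0), stringsAsFactors = FALSE)
  for (f in cand) {
    block <- NULL
    for (g in accepted) {
      r <- stats::cor(tm$x[, f], tm$x[, g])
      if (is.finite(r) && abs(r) > threshold) { block <- c(g, r); break }
    }
    if (is.null(block)) {
      accepted <- c(accepted, f)
    } else {
      removed <- rbind(removed, data.frame(feature = f, blocked_by = block[1],
                                           correlation = as.numeric(block[2]),
                                           stringsAsFactors = FALSE))
    }
  }
  list(accepted = accepted, removed = removed)
}

#' Greedy stepwise classifier-subset search
#'
#' Wrapper feature-subset selection in the classifier-subset-evaluator style:
#' starting from the empty set, each forward step adds the candidate that
#' maximizes stratified k-fold cross-validated accuracy of `spec`; after each
#' accepted addition, backward steps remove any feature whose removal does
#' not reduce accuracy. The search stops when no addition strictly improves
#' the best accuracy. Folds are fixed by `seed`, and ties are broken by
#' feature name, so the search is deterministic.
#'
#' @param table feature table.
#' @param labels class labels (defaults to the `condition` column).
#' @param spec a [classifier_spec()].
#' @param candidates character vector of candidate features (default: all).
#' @param folds CV folds (default 10).
#' @param seed seed fixing the fold assignment.
#' @return List: `subset` (character), `accuracy` (final CV accuracy, %),
#'   `trace` (data.frame of accepted steps).
#' @export
greedy_subset <- function(table, labels = NULL, spec = classifier_spec("svm"),
                          candidates = NULL, folds = 10L, seed = 1) {
  tm <- table_matrix(table)
  labels <- labels %||% tm$condition
  if (length(unique(labels)) != 2L) stop_frphrv("greedy search needs 2 classes")
  candidates <- candidates %||% colnames(tm$x)
  fold_id <- make_folds(labels, folds, seed)
  score <- function(feats) {
    cv_accuracy(tm$x[, feats, drop = FALSE], labels, spec, fold_id)
  }
  subset <- character(0)
  # baseline: majority-class accuracy of the empty model
  best <- 100 * max(table(labels)) / length(labels)
  trace <- data.frame(action = character(0), feature = character(0),
                      accuracy = numeric(0), stringsAsFactors = FALSE)
  repeat {
    remaining <- sort(setdiff(candidates, subset))
    if (length(remaining) == 0L) break
    accs <- vapply(remaining, function(f) score(c(subset, f)), numeric(1))
    top <- remaining[which.max(accs)]   # which.max takes the first (name order)
    if (max(accs) <= best) break
    subset <- c(subset, top)
    best <- max(accs)
    trace <- rbind(trace, data.frame(action = "add", feature = top,
                                     accuracy = best, stringsAsFactors = FALSE))
    # backward pass: drop anything whose removal does not reduce accuracy
    repeat {
      if (length(subset) <= 1L) break
      drop_accs <- vapply(sort(subset), function(f) {
        score(setdiff(subset, f))
      }, numeric(1))
      ok <- drop_accs >= best
      if (!any(ok)) break
      victim <- names(drop_accs)[ok][which.max(drop_accs[ok])]
      subset <- setdiff(subset, victim)
      best <- drop_accs[victim]
      trace <- rbind(trace, data.frame(action = "remove", feature = victim,
                                       accuracy = unname(best),
                                       stringsAsFactors = FALSE))
    }
  }
  list(subset = subset, accuracy = unname(best), trace = trace)
}

#' The full selection cascade
#'
#' z-score -> FDR ranking (threshold 0.95) -> correlation filter (0.9) ->
#' greedy stepwise subset per classifier, with each stage's output a subset
#' of its input.
#'
#' @param table feature table with a `condition` column.
#' @param specs list of [classifier_spec()]s for the greedy stage.
#' @param fdr_threshold,cor_threshold cascade thresholds.
#' @param folds,seed CV setup for the greedy stage.
#' @return An object of class `selection_result`: `ranking`, `fdr_survivors`,
#'   `nonredundant`, `removed`, `greedy` (named list per classifier),
#'   `zscore_params`.
#' @export
select_features <- function(table, specs = list(classifier_spec("svm")),
                            fdr_threshold = 0.95, cor_threshold = 0.9,
                            folds = 10L, seed = 1) {
  z <- zscore(table)
  ranking <- fdr_rank(z, threshold = fdr_threshold)
  cf <- correlation_filter(z, ranking, threshold = cor_threshold)
  greedy <- lapply(specs, function(sp) {
    g <- greedy_subset(z, spec = sp, candidates = cf$accepted,
                       folds = folds, seed = seed)
    g
  })
  names(greedy) <- vapply(specs, function(sp) sp$name, character(1))
  structure(list(ranking = ranking,
                 fdr_survivors = ranking$feature[ranking$survivor],
                 nonredundant = cf$accepted,
                 removed = cf$removed,
                 greedy = greedy,
                 zscore_params = attr(z, "zscore_params")),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("Selection cascade: %d ranked -> %d FDR survivors -> %d nonredundant\n",
              nrow(x$ranking), length(x$fdr_survivors), length(x$nonredundant)))
  cat("  nonredundant:", paste(x$nonredundant, collapse = ", "), "\n")
  for (nm in names(x$greedy)) {
    g <- x$greedy[[nm]]
    cat(sprintf("  greedy [%s]: {%s} at %.1f%% CV accuracy\n", nm,
                paste(g$subset, collapse = ", "), g$accuracy))
  }
  invisible(x)
}
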