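#' Classifier specification
#'
#' Constructs one of the six supported classifier configurations. The
#' positive class throughout evaluation is `"slow_paced"` (relaxation
#' detected). Hyperparameters: SVM uses an RBF kernel; kNN uses k = 3; the
#' decision tree uses CART with minimum bucket 2; the MLP is a single hidden
#' layer (size 3) trained up to 500 iterations; the random forest grows 100
#' trees.
#'
#' @param name one of `"svm"`, `"lda"`, `"ibk"`, `"dt"`, `"mlp"`, `"rf"`.
#' @param seed seed used by stochastic learners (MLP, RF).
#' @param ... hyperparameter overrides stored on the spec.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(name = c("svm", "lda", "ibk", "dt", "mlp", "rf"),
                            seed = 1, ...) {
  name <- match.arg(name)
  defaults <- switch(name,
    svm = list(kernel = "radial"),
    lda = list(),
    ibk = list(k = 3L),
    dt = list(minbucket = 2L),
    mlp = list(size = 3L, maxit = 500L, decay = 0),
    rf = list(ntree = 100L))
  structure(list(name = name, seed = seed,
                 params = utils::modifyList(defaults, list(...))),
            class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  ps <- if (length(x$params)) {
    paste(names(x$params), unlist(x$params), sep = "=", collapse = ", ")
  } else "defaults"
  cat(sprintf("Classifier spec: %s (%s)\n", toupper(x$name), ps))
  invisible(x)
}

# Fit `spec` on (x, y) and return scores (P(positive) or a monotone decision
# value) and predicted labels for x_test. y is a factor with the positive
# class as its second level.
fit_predict <- function(spec, x_train, y_train, x_test) {
  pos <- levels(y_train)[2]
  df_train <- as.data.frame(x_train)
  df_test <- as.data.frame(x_test)
  colnames(df_test) <- colnames(df_train)
  switch(spec$name,
    svm = {
      fit <- e1071::svm(x = x_train, y = y_train, kernel = spec$params$kernel,
                        probability = FALSE)
      pred <- stats::predict(fit, x_test, decision.values = TRUE)
      dv <- drop(attr(pred, "decision.values"))
      # decision values are signed for the first class named in the colname
      if (!grepl(paste0("^", pos, "/"), colnames(attr(pred, "decision.values"))[1])) {
        dv <- -dv
      }
      list(label = pred, score = dv)
    },
    lda = {
      # collinearity warnings are routine for the tiny subset fits the
      # greedy search performs; the posterior is still usable
      fit <- suppressWarnings(MASS::lda(x_train, grouping = y_train))
      pr <- stats::predict(fit, x_test)
      list(label = pr$class, score = pr$posterior[, pos])
    },
    ibk = {
      pr <- class::knn(x_train, x_test, y_train, k = spec$params$k, prob = TRUE)
      win <- attr(pr, "prob")
      score <- ifelse(pr == pos, win, 1 - win)
      list(label = pr, score = score)
    },
    dt = {
      df_train$.y <- y_train
      fit <- rpart::rpart(.y ~ ., data = df_train, method = "class",
                          minbucket = spec$params$minbucket)
      prob <- stats::predict(fit, df_test, type = "prob")[, pos]
      lab <- factor(ifelse(prob > 0.5, pos, levels(y_train)[1]),
                    levels = levels(y_train))
      list(label = lab, score = prob)
    },
    mlp = {
      fit <- with_seed(spec$seed,
        nnet::nnet(x_train, class.ind(y_train), size = spec$params$size,
                   maxit = spec$params$maxit, decay = spec$params$decay,
                   softmax = TRUE, trace = FALSE))
      prob <- stats::predict(fit, x_test)[, pos]
      lab <- factor(ifelse(prob > 0.5, pos, levels(y_train)[1]),
                    levels = levels(y_train))
      list(label = lab, score = prob)
    },
    rf = {
      fit <- with_seed(spec$seed,
        randomForest::randomForest(x_train, y_train,
                                   ntree = spec$params$ntree))
      prob <- stats::predict(fit, x_test, type = "prob")[, pos]
      lab <- stats::predict(fit, x_test)
      list(label = lab, score = prob)
    })
}

class.ind <- function(y) {
  res <- matrix(0, length(y), nlevels(y), dimnames = list(NULL, levels(y)))
  res[cbind(seq_along(y), as.integer(y))] <- 1
  res
}

# Stratified fold assignment: within each class, shuffle and deal round-robin.
make_folds <- function(labels, k, seed) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

as_condition_factor <- function(labels, positive = "slow_paced") {
  labs <- as.character(labels)
  cls <- unique(labs)
  if (length(cls) != 2L) stop_frphrv("binary classification needs 2 classes")
  neg <- setdiff(cls, positive)
  if (length(neg) == 2L) { neg <- sort(cls)[1]; positive <- sort(cls)[2] }
  factor(labs, levels = c(neg, positive))
}

# Plain CV accuracy (%) under a fixed fold assignment; used by greedy search.
cv_accuracy <- function(x, labels, spec, fold_id) {
  y <- as_condition_factor(labels)
  correct <- 0L
  for (f in sort(unique(fold_id))) {
    te <- fold_id == f
    pr <- fit_predict(spec, x[!te, , drop = FALSE], y[!te],
                      x[te, , drop = FALSE])
    correct <- correct + sum(pr$label == y[te])
  }
  100 * correct / length(y)
}

#' Confusion-matrix performance metrics
#'
#' @param tp,fp,tn,fn confusion counts with `slow_paced` as positive class.
#' @return Named list: `accuracy`, `sensitivity`, `specificity` (all %),
#'   `f1` (fraction). Metrics with an undefined denominator are `NA`.
#' @export
metrics <- function(tp, fp, tn, fn) {
  n <- tp + fp + tn + fn
  if (n == 0) stop_frphrv("empty confusion matrix")
  list(accuracy = 100 * (tp + tn) / n,
       sensitivity = if (tp + fn == 0) NA_real_ else 100 * tp / (tp + fn),
       specificity = if (tn + fp == 0) NA_real_ else 100 * tn / (tn + fp),
       f1 = if (2 * tp + fp + fn == 0) NA_real_ else 2 * tp / (2 * tp + fp + fn))
}

# Rank-based AUC (equivalent to the trapezoidal ROC area, ties mid-ranked).
rank_auc <- function(scores, y_pos) {
  n1 <- sum(y_pos); n0 <- sum(!y_pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[y_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified k-fold cross-validation report
#'
#' Stratified folds (fixed by `seed`), per-fold fit/predict, pooled confusion
#' counts, and AUC computed from the pooled decision scores by the rank
#' formula.
#'
#' @param table feature table (or plain data.frame/matrix of features).
#' @param labels class labels; defaults to the `condition` column.
#' @param spec a [classifier_spec()].
#' @param features optional character vector restricting the feature columns.
#' @param k folds (default 10).
#' @param seed fold seed.
#' @return Object of class `eval_report`: metrics (%), `auc` (%), `f1`,
#'   confusion counts, `spec`, `features`.
#' @export
cross_validate <- function(table, labels = NULL, spec = classifier_spec("svm"),
                           features = NULL, k = 10L, seed = 1) {
  tm <- table_matrix(table)
  labels <- labels %||% tm$condition
  x <- tm$x
  if (!is.null(features)) x <- x[, features, drop = FALSE]
  y <- as_condition_factor(labels)
  if (length(y) < k) stop_frphrv("need at least k instances")
  fold_id <- make_folds(y, k, seed)
  pos <- levels(y)[2]
  scores <- numeric(length(y)); pred <- character(length(y))
  for (f in sort(unique(fold_id))) {
    te <- fold_id == f
    if (length(unique(y[!te])) < 2L) stop_frphrv("a training fold lost a class")
    pr <- fit_predict(spec, x[!te, , drop = FALSE], y[!te], x[te, , drop = FALSE])
    scores[te] <- pr$score
    pred[te] <- as.character(pr$label)
  }
  tp <- sum(pred == pos & y == pos); fp <- sum(pred == pos & y != pos)
  tn <- sum(pred != pos & y != pos); fn <- sum(pred != pos & y == pos)
  m <- metrics(tp, fp, tn, fn)
  structure(c(m, list(auc = 100 * rank_auc(scores, y == pos),
                      tp = tp, fp = fp, tn = tn, fn = fn,
                      spec = spec, features = colnames(x),
                      k = k, seed = seed)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("%s %d-fold CV on %d features: ACC %.1f%%, SEN %.1f%%, SPE %.1f%%, F1 %.3f, AUC %.1f%%\n",
              toupper(x$spec$name), x$k, length(x$features), x$accuracy,
              x$sensitivity, x$specificity, x$f1, x$auc))
  invisible(x)
}

#' Learning curves over holdout fractions
#'
#' For each classifier and each test-set (holdout) proportion, repeatedly
#' draws a stratified split, trains on the remainder, and records the
#' test-set error rate, averaged over `reps` repetitions.
#'
#' @inheritParams cross_validate
#' @param specs list of [classifier_spec()]s.
#' @param holdouts test-set proportions (default 0.9 down to 0.1).
#' @param reps repetitions per cell (default 20).
#' @return data.frame: `classifier`, `holdout_pct`, `error_rate` (%).
#' @export
learning_curve <- function(table, labels = NULL,
                           specs = list(classifier_spec("svm")),
                           features = NULL,
                           holdouts = seq(0.9, 0.1, by = -0.1),
                           reps = 20L, seed = 1) {
  tm <- table_matrix(table)
  labels <- labels %||% tm$condition
  x <- tm$x
  if (!is.null(features)) x <- x[, features, drop = FALSE]
  y <- as_condition_factor(labels)
  grid <- expand.grid(spec_i = seq_along(specs), holdout = holdouts)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    sp <- specs[[grid$spec_i[g]]]
    h <- grid$holdout[g]
    errs <- vapply(seq_len(reps), function(r) {
      te <- with_seed(derive_seed(seed, g * 1000 + r), {
        unlist(lapply(levels(y), function(cl) {
          idx <- which(y == cl)
          sample(idx, max(1L, round(h * length(idx))))
        }))
      })
      if (length(unique(y[-te])) < 2L) return(NA_real_)
      # a tiny training split can be degenerate for some learners
      pr <- tryCatch(fit_predict(sp, x[-te, , drop = FALSE], y[-te],
                                 x[te, , drop = FALSE]),
                     error = function(e) NULL)
      if (is.null(pr)) return(NA_real_)
      100 * mean(pr$label != y[te])
    }, numeric(1))
    data.frame(classifier = sp$name, holdout_pct = 100 * h,
               error_rate = mean(errs, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
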