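make_table <- function(x, labels = NULL) {
  df <- as.data.frame(x)
  if (!is.null(labels)) df <- cbind(condition = labels, df)
  df
}

test_that("z-scoring standardizes every column and stores the transform", {
  tab <- make_table(cbind(a = c(1, 2, 3), b = c(10, 0, 5)))
  z <- zscore(tab)
  expect_equal(z$a, c(-1, 0, 1))
  expect_true(all(abs(colMeans(z[c("a", "b")])) < 1e-9))
  expect_true(all(abs(apply(z[c("a", "b")], 2, sd) - 1) < 1e-9))
  # stored transform reproduces the standardized table
  z2 <- zscore(tab, params = attr(z, "zscore_params"))
  expect_equal(z2, z, ignore_attr = TRUE)
  # constant columns are dropped with a warning
  tab$c <- 7
  expect_warning(z3 <- zscore(tab), "constant")
  expect_false("c" %in% names(z3))
})

test_that("FDR scores follow the two-class discriminant formula", {
  lab <- rep(c("x", "y"), each = 4)
  set.seed(60)
  tab <- make_table(cbind(
    same = rep(c(5, 6, 7, 8), 2),              # identical distributions
    shifted = c(0.9, 1.1, 1.0, 1.0, 1.9, 2.1, 2.0, 2.0)
  ), lab)
  rk <- fdr_rank(tab, threshold = 0.95)
  expect_equal(rk$fdr[rk$feature == "same"], 0)
  row <- rk[rk$feature == "shifted", ]
  expect_equal(row$fdr, (row$mu1 - row$mu2)^2 / (row$var1 + row$var2),
               tolerance = 1e-12)
  # class means 1 and 2 with unit variances give FDR 0.5
  expect_equal(1^2 / (1 + 1), 0.5)
  set.seed(61)
  tab2 <- make_table(cbind(f = c(rnorm(200, 1, 1), rnorm(200, 2, 1))),
                     rep(c("x", "y"), each = 200))
  expect_equal(fdr_rank(tab2)$fdr, 0.5, tolerance = 0.2)
  # zero variance in both classes with distinct means ranks first as Inf
  tab3 <- make_table(cbind(flat = rep(c(0, 1), each = 3),
                           noisy = rnorm(6)), rep(c("x", "y"), each = 3))
  rk3 <- fdr_rank(tab3)
  expect_equal(rk3$feature[1], "flat")
  expect_equal(rk3$fdr[1], Inf)
})

test_that("FDR ranking is invariant to affine transforms applied to both classes", {
  set.seed(62)
  x <- matrix(rnorm(40 * 5), 40)
  colnames(x) <- paste0("f", 1:5)
  x[1:20, ] <- x[1:20, ] + rep(seq(0.2, 1, by = 0.2), each = 20)
  lab <- rep(c("x", "y"), each = 20)
  rk1 <- fdr_rank(make_table(x, lab))
  rk2 <- fdr_rank(make_table(sweep(x * 3.7, 2, c(1, -2, 0, 5, 100), `+`), lab))
  expect_equal(rk1$feature, rk2$feature)
  expect_equal(rk1$fdr, rk2$fdr, tolerance = 1e-9)
})

test_that("the correlation filter performs greedy acceptance in FDR order", {
  set.seed(63)
  n <- 60
  base <- rnorm(n)
  lab <- rep(c("x", "y"), each = n / 2)
  shift <- (lab == "y") * 2
  x <- cbind(best = base + shift + rnorm(n, 0, 0.2),
             dup = NA, ortho = rnorm(n) + shift, weak = rnorm(n) + 0.8 * shift)
  x[, "dup"] <- x[, "best"]                      # exact duplicate
  tab <- make_table(x, lab)
  rk <- fdr_rank(tab, threshold = 0)
  rk$survivor <- TRUE
  cf <- correlation_filter(tab, rk, threshold = 0.9)
  expect_true("dup" %in% cf$removed$feature)     # |r| = 1 blocks the duplicate
  expect_false("dup" %in% cf$accepted)
  expect_true(all(c("ortho", "weak") %in% cf$accepted) ||
                all(c("ortho", "weak") %in% c(cf$accepted, cf$removed$feature)))
  # oracle: hand-simulate the acceptance walk
  tm <- as.matrix(tab[-1])
  accepted <- character(0)
  for (f in rk$feature) {
    ok <- all(vapply(accepted, function(g) abs(cor(tm[, f], tm[, g])) <= 0.9,
                     logical(1)))
    if (ok) accepted <- c(accepted, f)
  }
  expect_identical(cf$accepted, accepted)
  # mutually orthogonal features are all kept
  ortho_tab <- make_table(diag(6) * 2 + matrix(rnorm(36, 0, 0.01), 6), NULL)
  rko <- data.frame(feature = names(ortho_tab), survivor = TRUE)
  expect_length(correlation_filter(ortho_tab, rko)$accepted, 6)
})

test_that("greedy search finds a perfectly separating single feature", {
  tab <- separable_table()
  g <- greedy_subset(tab, spec = classifier_spec("lda"), folds = 5, seed = 3)
  expect_identical(g$subset, "signal")
  expect_gt(g$accuracy, 95)
})

test_that("greedy search terminates near chance on all-noise features", {
  set.seed(64)
  tab <- data.frame(condition = rep(c("a", "b"), each = 20),
                    matrix(rnorm(40 * 3), 40,
                           dimnames = list(NULL, c("n1", "n2", "n3"))))
  g <- greedy_subset(tab, spec = classifier_spec("lda"), folds = 5, seed = 4)
  expect_lte(length(g$subset), 1)
  expect_lt(g$accuracy, 75)
})

test_that("greedy search is within one fold-step of the exhaustive optimum", {
  set.seed(65)
  n <- 40
  lab <- rep(c("a", "b"), each = n / 2)
  shift <- (lab == "b") * 1.2
  x <- cbind(f1 = rnorm(n) + shift, f2 = rnorm(n) + 0.7 * shift,
             f3 = rnorm(n), f4 = rnorm(n) + 0.3 * shift)
  tab <- data.frame(condition = lab, x)
  spec <- classifier_spec("lda")
  g <- greedy_subset(tab, spec = spec, folds = 5, seed = 6)
  # exhaustive oracle over all 15 non-empty subsets with the same folds
  feats <- colnames(x)
  fold_id <- frphrv:::make_folds(lab, 5, 6)
  best <- 0
  for (k in 1:4) {
    for (s in utils::combn(feats, k, simplify = FALSE)) {
      acc <- frphrv:::cv_accuracy(x[, s, drop = FALSE], lab, spec, fold_id)
      best <- max(best, acc)
    }
  }
  expect_gte(g$accuracy, best - 100 / n)
})

test_that("the cascade is monotone and reproduces structural FDR identities", {
  tab <- separable_table(n_per_class = 20, p_noise = 4)
  sel <- select_features(tab, specs = list(classifier_spec("lda")),
                         folds = 5, seed = 7)
  expect_true(all(sel$fdr_survivors %in% sel$ranking$feature))
  expect_true(all(sel$nonredundant %in% sel$fdr_survivors))
  expect_true(all(sel$greedy$lda$subset %in% sel$nonredundant))
  # complementary normalized units always tie in FDR
  set.seed(66)
  lfnu <- runif(30, 20, 80)
  tab2 <- data.frame(condition = rep(c("a", "b"), 15),
                     lf_nu = lfnu, hf_nu = 100 - lfnu)
  rk <- fdr_rank(tab2, threshold = 0.95)
  expect_equal(rk$fdr[rk$feature == "lf_nu"], rk$fdr[rk$feature == "hf_nu"],
               tolerance = 1e-12)
})
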