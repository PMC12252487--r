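test_that("confusion metrics follow their defining ratios", {
  m <- metrics(30, 0, 30, 0)
  expect_equal(unlist(m), c(accuracy = 100, sensitivity = 100,
                            specificity = 100, f1 = 1))
  m2 <- metrics(28, 0, 30, 2)
  expect_equal(m2$sensitivity, 100 * 28 / 30, tolerance = 1e-12)
  expect_equal(m2$specificity, 100)
  expect_equal(m2$accuracy, 100 * 58 / 60, tolerance = 1e-12)
  # everything predicted positive on a balanced set
  m3 <- metrics(30, 30, 0, 0)
  expect_equal(m3$accuracy, 50)
  expect_equal(m3$specificity, 0)
  # undefined denominators flag as NA, not zero
  expect_true(is.na(metrics(0, 2, 3, 0)$sensitivity))
  # acc = (sen*P + spe*N) / (P + N) identically
  set.seed(70)
  for (rep in 1:5) {
    cm <- sample(0:20, 4, replace = TRUE)
    if (cm[1] + cm[4] == 0 || cm[3] + cm[2] == 0) next
    mm <- metrics(cm[1], cm[2], cm[3], cm[4])
    P <- cm[1] + cm[4]; N <- cm[2] + cm[3]
    expect_equal(mm$accuracy, (mm$sensitivity * P + mm$specificity * N) / (P + N),
                 tolerance = 1e-9)
  }
})

test_that("stratified folds keep both classes in every training fold", {
  lab <- rep(c("a", "b"), c(30, 30))
  folds <- frphrv:::make_folds(lab, 10, 1)
  expect_equal(sort(unique(folds)), 1:10)
  for (f in 1:10) {
    expect_setequal(unique(lab[folds != f]), c("a", "b"))
  }
})

test_that("every classifier separates an easy table perfectly", {
  tab <- separable_table(gap = 10)
  for (nm in c("svm", "lda", "ibk", "dt", "mlp", "rf")) {
    cv <- cross_validate(tab, spec = classifier_spec(nm), k = 5, seed = 2)
    expect_gt(cv$accuracy, 95)
  }
})

test_that("cross-validation is deterministic under a fixed seed", {
  tab <- separable_table(gap = 2)
  a <- cross_validate(tab, spec = classifier_spec("svm", seed = 5), seed = 9)
  b <- cross_validate(tab, spec = classifier_spec("svm", seed = 5), seed = 9)
  expect_identical(a[c("accuracy", "sensitivity", "specificity", "auc")],
                   b[c("accuracy", "sensitivity", "specificity", "auc")])
  rf1 <- cross_validate(tab, spec = classifier_spec("rf", seed = 5), seed = 9)
  rf2 <- cross_validate(tab, spec = classifier_spec("rf", seed = 5), seed = 9)
  expect_identical(rf1$accuracy, rf2$accuracy)
})

test_that("label-shuffled data scores at chance", {
  set.seed(71)
  n <- 2000
  x <- matrix(rnorm(n * 3), n, dimnames = list(NULL, c("a", "b", "c")))
  tab <- data.frame(condition = sample(rep(c("x", "y"), n / 2)), x)
  cv <- cross_validate(tab, spec = classifier_spec("lda"), seed = 3)
  expect_lt(abs(cv$accuracy - 50), 4)
  expect_lt(abs(cv$auc - 50), 4)
})

test_that("rank AUC matches the ROC area of an independent implementation", {
  set.seed(72)
  y <- rep(c(FALSE, TRUE), each = 40)
  scores <- rnorm(80) + y * 1.2
  ours <- frphrv:::rank_auc(scores, y)
  ref <- as.numeric(pROC::auc(pROC::roc(y, scores, quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
  expect_equal(frphrv:::rank_auc(seq_len(10), rep(c(FALSE, TRUE), each = 5)), 1)
})

test_that("learning curves are flat at zero for separable data", {
  tab <- separable_table(gap = 10)
  lc <- learning_curve(tab, specs = list(classifier_spec("lda")),
                       features = "signal", reps = 3, seed = 4)
  expect_true(all(lc$error_rate < 5))
  expect_equal(nrow(lc), 9)
  # single-rep runs are reproducible
  l1 <- learning_curve(tab, specs = list(classifier_spec("svm")), reps = 1,
                       seed = 8)
  l2 <- learning_curve(tab, specs = list(classifier_spec("svm")), reps = 1,
                       seed = 8)
  expect_identical(l1, l2)
})
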