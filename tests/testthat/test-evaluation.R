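test_that("stratified folds preserve class proportions to within one instance", {
  labs <- rep(c("A", "B"), each = 10)
  f <- stratified_kfold(labs, k = 5, seed = 1)
  tab <- table(labs, f)
  expect_true(all(tab == 2L))

  labs2 <- c(rep("A", 7), rep("B", 3))
  f2 <- stratified_kfold(labs2, k = 3, seed = 1)
  expect_identical(unname(table(labs2, f2)["B", ]), rep(1L, 3))
  perA <- table(labs2, f2)["A", ]
  expect_true(max(perA) - min(perA) <= 1)
})

test_that("fold assignment is deterministic under a fixed seed", {
  labs <- sample(c("x", "y", "z"), 200, replace = TRUE)
  expect_identical(stratified_kfold(labs, 10, seed = 5),
                   stratified_kfold(labs, 10, seed = 5))
  expect_false(identical(stratified_kfold(labs, 10, seed = 5),
                         stratified_kfold(labs, 10, seed = 6)))
})

test_that("k beyond the smallest class warns instead of erroring", {
  labs <- c(rep("A", 20), rep("B", 3))
  expect_warning(f <- stratified_kfold(labs, k = 5, seed = 1),
                 "smallest class")
  expect_identical(sort(unique(f)), 1:5)
})

test_that("confusion matrix counts by true row and predicted column", {
  cm <- confusion_matrix(c("a", "a", "b"), c("a", "b", "b"),
                         classes = c("a", "b"))
  expect_identical(cm, matrix(c(1L, 0L, 1L, 1L), 2,
                              dimnames = list(truth = c("a", "b"),
                                              predicted = c("a", "b"))))
  expect_identical(sum(cm), 3L)
  expect_error(confusion_matrix("a", c("a", "b")), "equal length")
  expect_error(confusion_matrix("a", "q", classes = c("a", "b")),
               "unknown label")
  # all-correct predictions give a diagonal matrix
  cm2 <- confusion_matrix(c("a", "b", "b"), c("a", "b", "b"))
  expect_identical(sum(cm2) - sum(diag(cm2)), 0L)
})

test_that("balanced accuracy is the unweighted mean of per-class recall", {
  cm <- matrix(c(8, 2, 0, 10), 2, byrow = TRUE,
               dimnames = list(c("p", "n"), c("p", "n")))
  sens <- per_class_sensitivity(cm)
  expect_equal(unname(sens), c(0.8, 1.0))
  expect_equal(balanced_accuracy(cm), 0.9)
  # perfect predictions
  expect_equal(balanced_accuracy(diag(c(5, 9, 2))), 1)
})

test_that("two-class BA equals (sensitivity + specificity) / 2 identically", {
  withr::with_seed(31, {
    for (rep in 1:25) {
      cm <- matrix(sample(1:50, 4, replace = TRUE), 2)
      sens <- cm[1, 1] / sum(cm[1, ])
      spec <- cm[2, 2] / sum(cm[2, ])
      expect_equal(balanced_accuracy(cm), (sens + spec) / 2)
    }
  })
})

test_that("classes without true instances are excluded with a warning", {
  cm <- matrix(c(5L, 0L, 0L, 0L), 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  expect_warning(ba <- balanced_accuracy(cm), "excluded")
  expect_equal(ba, 1)
})

test_that("a constant classifier scores 1/c on balanced data", {
  truth <- rep(c("a", "b", "c"), each = 10)
  pred <- rep("a", 30)
  cm <- confusion_matrix(truth, pred, classes = c("a", "b", "c"))
  expect_equal(balanced_accuracy(cm), 1 / 3)
})

test_that("imbalance ratio is majority over minority", {
  expect_equal(imbalance_ratio(rep(c("a", "b"), each = 25)), 1)
  expect_equal(round(imbalance_ratio(rep(c("a", "b"), c(170, 30))), 2), 5.67)
  expect_equal(imbalance_ratio(rep(c("a", "b", "c"), c(3, 1, 1))), 3)
  expect_error(imbalance_ratio(rep("a", 5)), "two classes")
})

test_that("cross-validation runs end to end on a tiny two-class table", {
  d <- data.frame(f1 = c(0.28, 0.21, 0.06, -0.24, 0.07),
                  f2 = c(0.17, 0.09, -0.15, 0.01, -0.28),
                  class = c("A", "A", "B", "B", "B"),
                  stringsAsFactors = FALSE)
  expect_no_error(suppressWarnings(
    res <- run_cv(d, label = "class", n = 1, k = 2, seed = 1)))
  expect_length(res$fold_ba, 2)
  expect_true(all(res$fold_ba >= 0 & res$fold_ba <= 1))
})

test_that("CV reaches BA 1.0 on a separable synthetic dataset", {
  d <- simulate_table(n_samples = 200, n_classes = 2, ir = 2,
                      n_numeric = 4, n_categorical = 2,
                      separation = 8, missing_rate = 0, seed = 7)
  res <- run_cv(d, label = "class", n = 3, k = 10, seed = 1)
  expect_equal(res$mean_ba, 1.0)
})

test_that("test-fold outliers never reach the fitted statistics or widths", {
  d <- simulate_table(n_samples = 100, separation = 6, missing_rate = 0,
                      seed = 8)
  folds <- stratified_kfold(d$class, k = 5, seed = 2)
  train <- d[folds != 1, ]
  test <- d[folds == 1, ]
  model <- nsbc_fit(train, label = "class", n = 3)
  clean_pred <- predict(model, test)
  # poison one held-out row with an extreme outlier: the model was fitted
  # before the test fold is even looked at, the outlier is clipped into
  # the training range at transform time, and every other row's
  # prediction is untouched
  poisoned <- test
  poisoned$num1[1] <- 1e6
  expect_no_error(pp <- predict(model, poisoned))
  expect_identical(pp[-1], clean_pred[-1])
  # and the full CV driver runs the poisoned table without error
  d2 <- d
  d2$num1[which(folds == 1)[1]] <- 1e6
  expect_no_error(run_cv(d2, label = "class", n = 3, k = 5, seed = 2))
})
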