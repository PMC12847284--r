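#' Stratified k-fold assignment
#'
#' Shuffles the indices of each class with a seeded RNG and deals them
#' round-robin to folds, so per-class fold counts differ by at most one and
#' every fold approximately preserves the overall class proportions.
#'
#' @param labels Class label per instance.
#' @param k Number of folds (`>= 2`).
#' @param seed Integer seed; the same labels and seed always give the same
#'   assignment.
#' @return Integer vector of fold ids in `1..k`, one per instance.
#' @export
stratified_kfold <- function(labels, k, seed = 1L) {
  labels <- as.character(labels)
  k <- as.integer(k)
  if (k < 2L) stop("`k` must be at least 2", call. = FALSE)
  counts <- table(labels)
  if (any(counts < 1L)) stop("every class needs an instance", call. = FALSE)
  if (k > min(counts)) {
    warning(sprintf("k = %d exceeds the smallest class count (%d); %s",
                    k, min(counts), "some folds will lack that class"),
            call. = FALSE)
  }
  folds <- integer(length(labels))
  with_seed(derive_seed(seed, "cv-shuffle"), {
    for (cls in sort(unique(labels))) {
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Confusion matrix with a fixed class order
#'
#' @param truth,predicted Equal-length label vectors.
#' @param classes Class order for rows/columns; defaults to the sorted
#'   union of observed labels. Any label outside `classes` is an error.
#' @return A `c x c` integer matrix; rows are true classes, columns
#'   predicted classes.
#' @export
confusion_matrix <- function(truth, predicted, classes = NULL) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) {
    stop("truth and predicted must have equal length", call. = FALSE)
  }
  if (is.null(classes)) classes <- sort(unique(c(truth, predicted)))
  bad <- setdiff(unique(c(truth, predicted)), classes)
  if (length(bad) > 0L) {
    stop(sprintf("unknown label token(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  tab <- table(factor(truth, levels = classes),
               factor(predicted, levels = classes))
  m <- matrix(as.integer(tab), nrow = length(classes),
              dimnames = list(truth = classes, predicted = classes))
  m
}

#' Per-class sensitivity (recall)
#'
#' `sensitivity_i = diagonal_i / row-sum_i`. Classes with an empty row
#' (no true instances) are excluded with a warning.
#'
#' @param cm A square confusion matrix (rows = truth).
#' @return Named numeric vector over the represented classes.
#' @export
per_class_sensitivity <- function(cm) {
  cm <- as.matrix(cm)
  stopifnot(nrow(cm) == ncol(cm))
  n_i <- rowSums(cm)
  empty <- n_i == 0
  if (any(empty)) {
    warning(sprintf("class(es) with no true instances excluded: %s",
                    paste(rownames(cm)[empty], collapse = ", ")),
            call. = FALSE)
  }
  diag(cm)[!empty] / n_i[!empty]
}

#' Balanced accuracy
#'
#' The unweighted mean of per-class sensitivities (macro recall). For a
#' two-class matrix this equals (sensitivity + specificity) / 2.
#'
#' @inheritParams per_class_sensitivity
#' @return A number in `[0, 1]`.
#' @export
balanced_accuracy <- function(cm) {
  mean(per_class_sensitivity(cm))
}

#' Imbalance ratio of a label vector
#'
#' Majority-class count divided by minority-class count; 1 for perfectly
#' balanced data. For more than two classes the largest and smallest class
#' counts are used.
#'
#' @param labels Class label per instance (at least two classes).
#' @return A number `>= 1`.
#' @export
imbalance_ratio <- function(labels) {
  counts <- table(as.character(labels))
  if (length(counts) < 2L) {
    stop("imbalance ratio needs at least two classes", call. = FALSE)
  }
  as.numeric(max(counts) / min(counts))
}

#' Stratified cross-validation of the n-SBC classifier
#'
#' Runs stratified k-fold cross-validation: for each fold, the
#' preprocessing statistics, bit widths and memory matrix are fitted on
#' the training folds only, and the held-out fold is predicted. Balanced
#' accuracy is computed per fold over the classes represented in that
#' fold's test set (a warning is issued if any fold misses a class).
#'
#' @param data Labeled data.frame.
#' @param label Label column name; defaults to the last column.
#' @param n Top-n aggregation count.
#' @param k Number of folds (default 10).
#' @param seed Seed for the fold shuffle.
#' @param encoding,missing_markers,categorical Passed to [nsbc_fit()].
#' @return An object of class `nsbc_cv`: `fold_ba` (per-fold balanced
#'   accuracy), `mean_ba`, `accuracy` (overall plain accuracy), `ir`,
#'   `folds`, `confusion` (pooled over folds), and the call parameters.
#' @export
run_cv <- function(data, label = NULL, n = 3L, k = 10L, seed = 1L,
                   encoding = "gray",
                   missing_markers = c("", "NA", "?", "nan"),
                   categorical = character()) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  label <- resolve_label(data, label)
  y <- trimws(as.character(data[[label]]))
  classes <- sort(unique(y))
  folds <- stratified_kfold(y, k = k, seed = seed)

  fold_ba <- numeric(k)
  pooled <- matrix(0L, nrow = length(classes), ncol = length(classes),
                   dimnames = list(truth = classes, predicted = classes))
  for (f in seq_len(k)) {
    test <- folds == f
    model <- nsbc_fit(data[!test, , drop = FALSE], label = label, n = n,
                      encoding = encoding,
                      missing_markers = missing_markers,
                      categorical = categorical)
    pred <- predict(model, data[test, , drop = FALSE], n = n)
    cm <- confusion_matrix(y[test], pred, classes = classes)
    fold_ba[f] <- balanced_accuracy(cm)
    pooled <- pooled + cm
  }

  structure(
    list(
      fold_ba = fold_ba,
      mean_ba = mean(fold_ba),
      accuracy = sum(diag(pooled)) / sum(pooled),
      ir = imbalance_ratio(y),
      folds = folds,
      confusion = pooled,
      n = n, k = k, seed = seed, label = label, classes = classes
    ),
    class = "nsbc_cv"
  )
}

#' @export
print.nsbc_cv <- function(x, ...) {
  cat(sprintf("Stratified %d-fold CV of %d-SBC (seed %d)\n", x$k, x$n, x$seed))
  cat(sprintf("  mean balanced accuracy: %.3f\n", x$mean_ba))
  cat(sprintf("  per-fold BA: %s\n", paste(sprintf("%.3f", x$fold_ba),
                                           collapse = " ")))
  cat(sprintf("  overall accuracy: %.3f; imbalance ratio: %.2f\n",
              x$accuracy, x$ir))
  invisible(x)
}
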