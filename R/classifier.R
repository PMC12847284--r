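#' Hamming distance between equal-length bit strings
#'
#' @param a,b Bit patterns, each either a character string of 0/1 or an
#'   integer 0/1 vector. Lengths must match.
#' @return Nonnegative integer: the number of differing positions.
#' @examples
#' hamming("110010", "101111")  # 4
#' @export
hamming <- function(a, b) {
  a <- as_bitvec(a)
  b <- as_bitvec(b)
  if (length(a) != length(b)) {
    stop("bit strings must have equal length", call. = FALSE)
  }
  sum(bitwXor(a, b))
}

#' @keywords internal
#' @noRd
as_bitvec <- function(x) {
  if (is.character(x)) {
    stopifnot(length(x) == 1L)
    x <- as.integer(strsplit(x, "", fixed = TRUE)[[1L]])
  }
  x <- as.integer(x)
  if (any(!x %in% c(0L, 1L))) stop("bits must be 0 or 1", call. = FALSE)
  x
}

#' Fit an n-SBC model
#'
#' The n-similarity binary classifier stores every Gray-encoded training
#' pattern verbatim in a memory matrix, together with its class label; no
#' further optimisation happens at training time. Classification scores a
#' query against each class by summing the `n` largest Hamming similarities
#' `z = u - H` between the query and the class's stored patterns (`u` is
#' the common bit length), and predicts the class with the largest sum.
#' Because only the best `n` matches per class count, a large majority
#' class cannot inflate its score through sheer prevalence.
#'
#' @param data Training data.frame with mixed numeric/categorical features
#'   and a label column.
#' @param label Label column name; defaults to the last column.
#' @param n Number of top matches aggregated per class. The natural range
#'   is `1 <= n <= K_min` (the smallest class size); larger `n` is clamped
#'   per class with a warning at prediction time.
#' @param encoding `"gray"` (default) or `"binary"` (ablation: plain
#'   fixed-width binary instead of reflected-binary code).
#' @param missing_markers,categorical Passed to [fit_preprocessor()].
#' @return An object of class `nsbc` holding the preprocessing model, the
#'   bit-width profile, the memory matrix of encoded patterns, the class
#'   labels, class counts `K` and `K_min`, and the default `n`.
#' @examples
#' d <- simulate_table(n_samples = 60, seed = 1)
#' m <- nsbc_fit(d, label = "class", n = 3)
#' predict(m, d[1:5, ])
#' @export
nsbc_fit <- function(data, label = NULL, n = 3L,
                     encoding = c("gray", "binary"),
                     missing_markers = c("", "NA", "?", "nan"),
                     categorical = character()) {
  encoding <- match.arg(encoding)
  pre <- fit_preprocessor(data, label = label,
                          missing_markers = missing_markers,
                          categorical = categorical)
  if (is.na(pre$label)) stop("training data needs a label column", call. = FALSE)
  tr <- transform_table(pre, data)
  profile <- fit_widths(tr$x)
  bits <- encode_matrix(tr$x, profile, encoding = encoding)
  nsbc_from_bits(bits, tr$y, profile = profile, n = n,
                 preproc = pre, encoding = encoding)
}

#' Build an n-SBC model directly from encoded bit patterns
#'
#' Lower-level constructor used when patterns are already binary (e.g.
#' externally encoded data or hand-built examples). `nsbc_fit()` calls it
#' after preprocessing and Gray encoding.
#'
#' @param bits Either a character vector of equal-length 0/1 strings or an
#'   integer 0/1 matrix, one pattern per row.
#' @param labels Class label per pattern.
#' @param profile Optional `nsbc_widths` segment profile; defaults to one
#'   segment spanning all bits.
#' @param n Default top-n aggregation count.
#' @param preproc Optional fitted `nsbc_preproc` (present when built by
#'   [nsbc_fit()]); `NULL` for raw-bit models.
#' @param encoding Encoding recorded for query-time use.
#' @return An `nsbc` model object.
#' @export
nsbc_from_bits <- function(bits, labels, profile = NULL, n = 3L,
                           preproc = NULL, encoding = "gray") {
  if (is.character(bits)) bits <- string_to_bits(bits)
  bits <- as.matrix(bits)
  storage.mode(bits) <- "integer"
  if (any(!bits %in% c(0L, 1L))) stop("patterns must be 0/1", call. = FALSE)
  if (nrow(bits) != length(labels)) {
    stop("one label per pattern is required", call. = FALSE)
  }
  labels <- as.character(labels)
  if (anyNA(labels)) stop("labels may not be missing", call. = FALSE)
  class_names <- sort(unique(labels))
  if (length(class_names) < 2L) {
    stop("training data must contain at least two classes", call. = FALSE)
  }
  y <- factor(labels, levels = class_names)
  K <- as.integer(table(y))
  names(K) <- class_names
  if (any(K < 1L)) stop("every class needs at least one pattern", call. = FALSE)
  if (is.null(profile)) profile <- new_widths(ncol(bits), "pattern")
  if (profile$total_bits != ncol(bits)) {
    stop("profile bit count does not match the patterns", call. = FALSE)
  }
  if (n < 1L) stop("`n` must be a positive integer", call. = FALSE)

  structure(
    list(
      bits = bits,
      labels = y,
      class_names = class_names,
      K = K,
      K_min = min(K),
      u = ncol(bits),
      n = as.integer(n),
      profile = profile,
      preproc = preproc,
      encoding = encoding
    ),
    class = "nsbc"
  )
}

#' @export
print.nsbc <- function(x, ...) {
  cat(sprintf("n-SBC model (n = %d): %d stored patterns, %d classes, u = %d bits\n",
              x$n, nrow(x$bits), length(x$class_names), x$u))
  cat("Class counts:",
      paste(sprintf("%s=%d", x$class_names, x$K), collapse = ", "),
      sprintf("(K_min = %d)\n", x$K_min))
  invisible(x)
}

#' Similarity of a query to every stored pattern
#'
#' Returns `z[mu] = u - H(query, pattern[mu])` for each training pattern,
#' in stored order: the number of bit positions at which the query agrees
#' with that pattern.
#'
#' @param model A fitted `nsbc` model.
#' @param query A single encoded query: 0/1 string or integer vector of
#'   length `model$u`.
#' @return Integer vector of similarities in `[0, u]`.
#' @export
similarity_vector <- function(model, query) {
  stopifnot(inherits(model, "nsbc"))
  q <- as_bitvec(query)
  if (length(q) != model$u) {
    stop(sprintf("query has %d bits; the memory stores %d-bit patterns",
                 length(q), model$u), call. = FALSE)
  }
  as.integer(model$u - hamming_to_memory(model$bits, matrix(q, nrow = 1L))[, 1L])
}

# pairwise Hamming distances between stored patterns (rows of M) and query
# rows of Q, via the popcount identity |a| + |b| - 2 a.b on 0/1 vectors
#' @keywords internal
#' @noRd
hamming_to_memory <- function(M, Q) {
  outer(rowSums(M), rowSums(Q), "+") - 2 * (M %*% t(Q))
}

#' Per-class top-n aggregated similarity scores
#'
#' For each class the `n` largest entries of the similarity vector among
#' that class's stored patterns are summed. When a class holds fewer than
#' `n` patterns, all of them are used and a warning is issued.
#'
#' @param model A fitted `nsbc` model.
#' @param z Integer similarity vector from [similarity_vector()].
#' @param n Top-n count; defaults to the model's `n`.
#' @return An object of class `nsbc_scores`: per-class `scores`, effective
#'   `n_used`, the selected pattern indices, the tie-aware `onehot`
#'   indicator and the `predicted` class (lowest class index among ties).
#' @export
class_scores <- function(model, z, n = model$n) {
  stopifnot(inherits(model, "nsbc"), length(z) == nrow(model$bits))
  n <- as.integer(n)
  if (n < 1L) stop("`n` must be >= 1", call. = FALSE)
  if (n > model$K_min) {
    warning(sprintf("n = %d exceeds the smallest class count K_min = %d; %s",
                    n, model$K_min,
                    "clamping to each class's size"), call. = FALSE)
  }
  cls <- model$class_names
  n_used <- pmin(n, model$K)
  selected <- vector("list", length(cls))
  scores <- numeric(length(cls))
  for (i in seq_along(cls)) {
    idx <- which(model$labels == cls[i])
    ord <- idx[order(z[idx], decreasing = TRUE)]
    take <- ord[seq_len(n_used[i])]
    selected[[i]] <- take
    scores[i] <- sum(z[take])
  }
  names(scores) <- cls
  names(selected) <- cls
  onehot <- as.integer(scores == max(scores))
  structure(
    list(scores = scores, n_used = n_used, selected = selected,
         onehot = stats::setNames(onehot, cls),
         predicted = cls[which.max(scores)]),
    class = "nsbc_scores"
  )
}

#' @export
print.nsbc_scores <- function(x, ...) {
  cat("Class scores (top-n aggregated similarity):\n")
  print(x$scores)
  if (sum(x$onehot) > 1L) {
    cat("Tie between:", paste(names(x$onehot)[x$onehot == 1L], collapse = ", "),
        "- predicting the lowest class index\n")
  }
  cat("Predicted:", x$predicted, "\n")
  invisible(x)
}

#' Predict class labels for new data
#'
#' @param object A fitted `nsbc` model.
#' @param newdata For models fitted by [nsbc_fit()], a data.frame with the
#'   training feature columns. For raw-bit models, a character vector of
#'   bit strings or a 0/1 matrix (one pattern per row).
#' @param n Top-n count; defaults to the model's `n`.
#' @param type `"class"` for a label vector, `"scores"` for the per-class
#'   score matrix (one row per query).
#' @param ... Unused.
#' @return Character vector of predicted labels, or a numeric score matrix.
#' @export
predict.nsbc <- function(object, newdata, n = object$n,
                         type = c("class", "scores"), ...) {
  type <- match.arg(type)
  Q <- encode_queries(object, newdata)
  n <- as.integer(n)
  if (n < 1L) stop("`n` must be >= 1", call. = FALSE)
  if (n > object$K_min) {
    warning(sprintf("n = %d exceeds K_min = %d; clamping per class",
                    n, object$K_min), call. = FALSE)
  }
  H <- hamming_to_memory(object$bits, Q)     # |L| x nq distances
  Z <- object$u - H                          # similarities
  cls <- object$class_names
  n_used <- pmin(n, object$K)
  S <- matrix(0, nrow = ncol(Z), ncol = length(cls),
              dimnames = list(NULL, cls))
  for (i in seq_along(cls)) {
    zi <- Z[object$labels == cls[i], , drop = FALSE]
    S[, i] <- apply(zi, 2L, function(col) {
      sum(sort(col, decreasing = TRUE)[seq_len(n_used[i])])
    })
  }
  if (type == "scores") return(S)
  cls[apply(S, 1L, which.max)]
}

#' @keywords internal
#' @noRd
encode_queries <- function(model, newdata) {
  if (is.null(model$preproc)) {
    if (is.character(newdata)) newdata <- string_to_bits(newdata)
    Q <- as.matrix(newdata)
    storage.mode(Q) <- "integer"
    if (ncol(Q) != model$u) {
      stop("query bit length does not match the memory", call. = FALSE)
    }
    Q
  } else {
    tr <- transform_table(model$preproc, newdata)
    encode_matrix(tr$x, model$profile, encoding = model$encoding)
  }
}
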