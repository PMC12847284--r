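#' Fit the preprocessing model on a training table
#'
#' Turns a raw mixed-type table into the statistics needed to map any row to
#' a nonnegative integer vector ready for Gray encoding. All statistics are
#' computed on the training data only and reapplied verbatim to queries, so
#' no test-fold information ever leaks into the model:
#'
#' * numeric columns: missing cells are imputed with the training mean;
#'   the training minimum (`min_shift`) is subtracted so values are
#'   nonnegative; each value is truncated to 2 decimal places and scaled
#'   by 100 to an integer.
#' * categorical columns: missing cells are imputed with the training mode
#'   (ties broken towards the lexicographically smallest token); categories
#'   are label-encoded in sorted token order with codes 0, 1, ..., then run
#'   through the same shift/scale step.
#'
#' At transform time, unseen category tokens fall back to the imputation
#' value's code, and numeric values outside the training range are clipped
#' to `[0, train_max_int]` so every value fits the bit widths fitted on the
#' training fold.
#'
#' @param data A data.frame. Cells may be numeric, category tokens, or
#'   missing (`NA` or any token in `missing_markers`).
#' @param label Name of the label column; defaults to the last column. Use
#'   `label = NA` for an unlabeled table.
#' @param missing_markers Character vector of tokens (matched
#'   case-insensitively after trimming) treated as missing.
#' @param categorical Optional character vector of feature names forced to
#'   be treated as categorical even if every token parses as a number.
#' @return An object of class `nsbc_preproc`.
#' @seealso [transform_table()], [fit_widths()]
#' @export
fit_preprocessor <- function(data, label = NULL,
                             missing_markers = c("", "NA", "?", "nan"),
                             categorical = character()) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (nrow(data) < 1L) stop("training table has no rows", call. = FALSE)
  label <- resolve_label(data, label)
  feat_names <- setdiff(names(data), label)
  if (length(feat_names) < 1L) {
    stop("training table has no feature columns", call. = FALSE)
  }

  if (!is.na(label)) {
    lab_raw <- normalize_column(data[[label]], missing_markers)
    if (anyNA(lab_raw)) {
      stop(sprintf("label column '%s' contains missing values", label),
           call. = FALSE)
    }
  }

  cols <- lapply(feat_names, function(nm) {
    fit_column(normalize_column(data[[nm]], missing_markers), nm,
               force_cat = nm %in% categorical)
  })
  names(cols) <- feat_names

  structure(
    list(
      columns = cols,
      feature_names = feat_names,
      label = label,
      scale = 100L,
      missing_markers = missing_markers
    ),
    class = "nsbc_preproc"
  )
}

# trims whitespace and maps missing markers to NA; always returns character
#' @keywords internal
#' @noRd
normalize_column <- function(x, missing_markers) {
  x <- trimws(as.character(x))
  x[is.na(x) | tolower(x) %in% tolower(missing_markers)] <- NA_character_
  x
}

#' @keywords internal
#' @noRd
fit_column <- function(tokens, name, force_cat = FALSE) {
  obs <- tokens[!is.na(tokens)]
  if (length(obs) == 0L) {
    stop(sprintf("column '%s' is entirely missing", name), call. = FALSE)
  }
  num <- suppressWarnings(as.numeric(obs))
  n_numeric <- sum(!is.na(num))
  if (!force_cat && n_numeric == length(obs)) {
    impute <- mean(num)
    filled <- ifelse(is.na(tokens), impute,
                     suppressWarnings(as.numeric(tokens)))
    min_shift <- min(filled)
    ints <- integerize(filled, min_shift)
    list(kind = "numeric", name = name, impute = impute,
         min_shift = min_shift, train_max_int = max(ints))
  } else if (force_cat || n_numeric == 0L) {
    counts <- table(obs)
    top <- max(counts)
    impute <- sort(names(counts)[counts == top])[1L]
    levels <- sort(unique(obs))
    codes <- stats::setNames(seq_along(levels) - 1L, levels)
    filled <- ifelse(is.na(tokens), impute, tokens)
    enc <- as.numeric(codes[filled])
    min_shift <- min(enc)
    ints <- integerize(enc, min_shift)
    list(kind = "categorical", name = name, impute = impute, codes = codes,
         min_shift = min_shift, train_max_int = max(ints))
  } else {
    stop(sprintf(
      "column '%s' mixes numeric and non-numeric cells (%d numeric of %d)",
      name, n_numeric, length(obs)), call. = FALSE)
  }
}

#' Shift, truncate and scale real values to nonnegative integers
#'
#' Each value `v` maps to `floor(trunc2(v - min_shift) * 100)` where
#' `trunc2` truncates toward minus infinity at 2 decimal places. The
#' arithmetic rounds away accumulated binary-float error before truncating
#' (at the 6th decimal of the scaled value), so e.g. a shifted value of
#' exactly 1.24 always yields 124, never 123.
#'
#' @param values Numeric vector (already imputed/encoded).
#' @param min_shift Shift subtracted before scaling; on training data this
#'   is the column minimum, making the results nonnegative.
#' @return Integer vector.
#' @export
integerize <- function(values, min_shift) {
  if (!is.numeric(values) || any(!is.finite(values))) {
    stop("values must be finite numerics", call. = FALSE)
  }
  as.integer(floor(round((values - min_shift) * 100, 6)))
}

#' Apply a fitted preprocessing model to a table
#'
#' @param model An `nsbc_preproc` object.
#' @param data A data.frame with the same feature columns as the training
#'   table (the label column may be absent).
#' @return A list with `x`, the nonnegative integer matrix (one row per
#'   record, feature order preserved), and `y`, the label tokens (or `NULL`
#'   when the table has no label column).
#' @export
transform_table <- function(model, data) {
  stopifnot(inherits(model, "nsbc_preproc"))
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  missing_cols <- setdiff(model$feature_names, names(data))
  if (length(missing_cols) > 0L) {
    stop(sprintf("table lacks feature column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  x <- matrix(0L, nrow = nrow(data), ncol = length(model$feature_names),
              dimnames = list(NULL, model$feature_names))
  for (nm in model$feature_names) {
    x[, nm] <- transform_column(model$columns[[nm]],
                                normalize_column(data[[nm]],
                                                 model$missing_markers))
  }
  y <- NULL
  if (!is.na(model$label) && model$label %in% names(data)) {
    y <- normalize_column(data[[model$label]], model$missing_markers)
    if (anyNA(y)) stop("label column contains missing values", call. = FALSE)
  }
  list(x = x, y = y)
}

#' @keywords internal
#' @noRd
transform_column <- function(col, tokens) {
  if (col$kind == "numeric") {
    vals <- suppressWarnings(as.numeric(tokens))
    bad <- !is.na(tokens) & is.na(vals)
    if (any(bad)) {
      stop(sprintf("column '%s': non-numeric cell '%s' in a numeric column",
                   col$name, tokens[bad][1L]), call. = FALSE)
    }
    vals[is.na(vals)] <- col$impute
    ints <- integerize(vals, col$min_shift)
  } else {
    tokens[is.na(tokens)] <- col$impute
    unseen <- !(tokens %in% names(col$codes))
    tokens[unseen] <- col$impute
    ints <- integerize(as.numeric(col$codes[tokens]), col$min_shift)
  }
  # clip to the training range so fitted bit widths always hold
  pmin(pmax(ints, 0L), col$train_max_int)
}

#' @export
print.nsbc_preproc <- function(x, ...) {
  kinds <- vapply(x$columns, `[[`, "", "kind")
  cat(sprintf("Preprocessing model: %d features (%d numeric, %d categorical)\n",
              length(kinds), sum(kinds == "numeric"),
              sum(kinds == "categorical")))
  if (!is.na(x$label)) cat("Label column:", x$label, "\n")
  invisible(x)
}

#' @keywords internal
#' @noRd
resolve_label <- function(data, label) {
  if (is.null(label)) label <- names(data)[ncol(data)]
  if (is.na(label)) return(NA_character_)
  if (!label %in% names(data)) {
    stop(sprintf("label column '%s' not found", label), call. = FALSE)
  }
  label
}
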