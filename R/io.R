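#' Read a delimited table for classification
#'
#' Reads a header-row CSV (or other delimiter) with every cell kept as
#' text; type inference and missing-value handling happen later in
#' [fit_preprocessor()], so numbers like "007" or tokens like "?" survive
#' unmangled.
#'
#' @param path File path.
#' @param delim Field delimiter (default comma).
#' @return A character data.frame.
#' @export
read_table_csv <- function(path, delim = ",") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  utils::read.table(path, header = TRUE, sep = delim, quote = "\"",
                    colClasses = "character", check.names = FALSE,
                    na.strings = NULL, comment.char = "",
                    stringsAsFactors = FALSE)
}

#' Read a WEKA ARFF file
#'
#' Thin wrapper over `foreign::read.arff()`; nominal attributes become
#' character columns and `?` cells arrive as `NA`.
#'
#' @param path File path.
#' @return A data.frame.
#' @export
read_table_arff <- function(path) {
  if (!requireNamespace("foreign", quietly = TRUE)) {
    stop("reading ARFF files requires the 'foreign' package", call. = FALSE)
  }
  df <- foreign::read.arff(path)
  for (j in seq_along(df)) {
    if (is.factor(df[[j]])) df[[j]] <- as.character(df[[j]])
  }
  df
}

#' Save / load an n-SBC model as JSON
#'
#' The whole model — preprocessing statistics, bit-width profile, memory
#' patterns (as 0/1 text strings), labels and the default `n` — is written
#' as a single JSON document with widths and segments as explicit
#' integers, so a reloaded model is bit-exact on any platform.
#'
#' @param model A fitted `nsbc` model.
#' @param path Destination file.
#' @return `save_model()` returns `path` invisibly; `load_model()` returns
#'   the reconstructed `nsbc` object.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "nsbc"))
  pre <- model$preproc
  doc <- list(
    format = "nsbc-model",
    version = 1L,
    n = model$n,
    encoding = model$encoding,
    u = model$u,
    labels = as.character(model$labels),
    patterns = unname(bits_to_string(model$bits)),
    widths = model$profile$widths,
    feature_names = model$profile$feature_names,
    preproc = if (is.null(pre)) NULL else serialize_preproc(pre)
  )
  write_atomic(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                                null = "null"), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  if (!identical(doc$format, "nsbc-model")) {
    stop("not an n-SBC model file", call. = FALSE)
  }
  profile <- new_widths(doc$widths, doc$feature_names)
  pre <- if (is.null(doc$preproc)) NULL else deserialize_preproc(doc$preproc)
  nsbc_from_bits(doc$patterns, doc$labels, profile = profile, n = doc$n,
                 preproc = pre, encoding = doc$encoding)
}

#' @keywords internal
#' @noRd
serialize_preproc <- function(pre) {
  list(
    label = pre$label,
    scale = pre$scale,
    missing_markers = pre$missing_markers,
    feature_names = pre$feature_names,
    columns = lapply(pre$columns, function(col) {
      out <- list(kind = col$kind, name = col$name,
                  impute = col$impute, min_shift = col$min_shift,
                  train_max_int = col$train_max_int)
      if (col$kind == "categorical") {
        out$levels <- names(col$codes)
        out$codes <- unname(col$codes)
      }
      out
    })
  )
}

#' @keywords internal
#' @noRd
deserialize_preproc <- function(doc) {
  cols <- lapply(doc$columns, function(col) {
    out <- list(kind = col$kind, name = col$name, impute = col$impute,
                min_shift = col$min_shift,
                train_max_int = as.integer(col$train_max_int))
    if (col$kind == "categorical") {
      out$codes <- stats::setNames(as.integer(col$codes), col$levels)
    }
    out
  })
  names(cols) <- doc$feature_names
  structure(
    list(columns = cols,
         feature_names = doc$feature_names,
         label = doc$label,
         scale = as.integer(doc$scale),
         missing_markers = doc$missing_markers),
    class = "nsbc_preproc"
  )
}

# write-then-rename so readers never observe a half-written file
#' @keywords internal
#' @noRd
write_atomic <- function(text, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  writeLines(text, tmp)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

#' @keywords internal
#' @noRd
write_csv_atomic <- function(df, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  utils::write.csv(df, tmp, row.names = FALSE, quote = TRUE, na = "")
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}
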