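#' Explain an n-SBC decision
#'
#' Produces the evidence behind a prediction: for every class, the top-n
#' stored patterns selected during scoring, their similarity values `z`,
#' the bitwise match-indicator against the query (1 where the query bit
#' agrees with the stored bit), and per-feature matched-bit counts over the
#' feature-aligned bit segments. The per-feature counts of each selected
#' pattern sum exactly to its `z`, so the report decomposes every score
#' into feature-level evidence.
#'
#' @param model A fitted `nsbc` model.
#' @param query One query: a data.frame row for models fitted from raw
#'   tables, or a bit string / 0/1 vector for raw-bit models.
#' @param n Top-n count; defaults to the model's `n`.
#' @return An object of class `nsbc_explanation` containing `query_bits`,
#'   `predicted`, `margin` (best score minus runner-up), per-class scores,
#'   and `evidence`, a data.frame with one row per selected pattern.
#' @examples
#' we <- worked_example()
#' m <- nsbc_from_bits(we$bit_strings, we$labels, profile = we$profile, n = 2)
#' explain(m, we$query_bits)
#' @export
explain <- function(model, query, n = model$n) {
  stopifnot(inherits(model, "nsbc"))
  Q <- encode_queries(model, query)
  if (nrow(Q) != 1L) stop("explain one query at a time", call. = FALSE)
  q <- Q[1L, ]
  z <- similarity_vector(model, q)
  sc <- class_scores(model, z, n = n)

  prof <- model$profile
  rows <- list()
  for (cls in model$class_names) {
    for (idx in sc$selected[[cls]]) {
      pat <- model$bits[idx, ]
      match_vec <- as.integer(pat == q)
      seg_matches <- vapply(seq_along(prof$widths), function(k) {
        cols <- prof$offsets[k] + seq_len(prof$widths[k])
        sum(match_vec[cols])
      }, 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        pattern = idx,
        class = cls,
        bits = bits_to_string(pat),
        match = bits_to_string(match_vec),
        z = z[idx],
        t(stats::setNames(seg_matches, paste0("match.", prof$feature_names))),
        check.names = FALSE,
        stringsAsFactors = FALSE
      )
    }
  }
  evidence <- do.call(rbind, rows)
  ord <- sort(sc$scores, decreasing = TRUE)
  margin <- if (length(ord) > 1L) ord[1L] - ord[2L] else ord[1L]

  structure(
    list(
      query_bits = bits_to_string(q),
      predicted = sc$predicted,
      margin = unname(margin),
      scores = sc$scores,
      n_used = sc$n_used,
      evidence = evidence
    ),
    class = "nsbc_explanation"
  )
}

#' @export
print.nsbc_explanation <- function(x, ...) {
  cat("Query bits :", x$query_bits, "\n")
  cat("Predicted  :", x$predicted,
      sprintf("(margin %g over runner-up)\n", x$margin))
  cat("Scores     :",
      paste(sprintf("%s=%g", names(x$scores), x$scores), collapse = ", "),
      "\n\nEvidence (selected top-n patterns per class):\n")
  print(x$evidence, row.names = FALSE)
  invisible(x)
}
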