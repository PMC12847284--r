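#' Simulate an imbalanced mixed-type clinical-style table
#'
#' Generates a small tabular dataset of the kind the classifier targets:
#' a few hundred to ~1,500 rows, 2-6 classes, imbalance ratios from 1 up
#' to ~31, a mix of numeric and categorical features, and a sprinkle of
#' missing cells. Numeric features are class-shifted Gaussians (class `j`
#' centred at `separation * (j - 1)`, unit spread); categorical features
#' concentrate a class-dependent preferred level with probability
#' `cat_affinity`, the remaining mass spread uniformly. Missing cells are
#' injected uniformly at random over the feature cells, never in the
#' label. Class sizes follow the requested proportions by largest-remainder
#' rounding, so they match exactly after rounding.
#'
#' @param n_samples Number of rows.
#' @param n_classes Number of classes (ignored when `class_props` given).
#' @param class_props Optional class proportions (summing to 1).
#' @param ir Optional two-class imbalance ratio (majority/minority);
#'   shorthand for `class_props = c(ir, 1)/(ir + 1)`.
#' @param n_numeric,n_categorical Feature counts of each kind.
#' @param n_levels Levels per categorical feature.
#' @param separation Distance between adjacent class centres, in units of
#'   the within-class standard deviation. Around 3 gives largely separable
#'   classes; 0 gives pure noise.
#' @param cat_affinity Probability mass on a class's preferred level of
#'   each categorical feature.
#' @param missing_rate Fraction of feature cells set missing.
#' @param seed Integer seed; fixes the whole table.
#' @return A data.frame with numeric columns `num1..`, categorical columns
#'   `cat1..` (letter tokens), and a final `class` label column
#'   (`c1..c<n>`; `c1` is the largest class).
#' @export
simulate_table <- function(n_samples = 200L, n_classes = 2L,
                           class_props = NULL, ir = NULL,
                           n_numeric = 4L, n_categorical = 2L,
                           n_levels = 3L, separation = 3,
                           cat_affinity = 0.7, missing_rate = 0.02,
                           seed = 1L) {
  if (!is.null(ir)) {
    stopifnot(is.null(class_props), ir >= 1)
    class_props <- c(ir, 1) / (ir + 1)
  }
  if (is.null(class_props)) class_props <- rep(1 / n_classes, n_classes)
  if (abs(sum(class_props) - 1) > 1e-8) {
    stop("class proportions must sum to 1", call. = FALSE)
  }
  n_classes <- length(class_props)
  counts <- largest_remainder(class_props, n_samples)
  if (any(counts == 0L)) {
    stop("requested proportions leave a class with zero samples",
         call. = FALSE)
  }
  if (n_numeric + n_categorical < 1L) {
    stop("at least one feature is required", call. = FALSE)
  }

  cls <- rep(paste0("c", seq_len(n_classes)), counts)
  with_seed(derive_seed(seed, "simulate"), {
    out <- list()
    for (f in seq_len(n_numeric)) {
      mu <- separation * (match(cls, unique(cls)) - 1L)
      out[[paste0("num", f)]] <- round(stats::rnorm(n_samples, mean = mu), 3)
    }
    lv <- letters[seq_len(n_levels)]
    for (f in seq_len(n_categorical)) {
      col <- character(n_samples)
      for (j in seq_len(n_classes)) {
        pref <- ((j - 1L + f - 1L) %% n_levels) + 1L
        w <- rep((1 - cat_affinity) / (n_levels - 1L), n_levels)
        if (n_levels == 1L) w <- 1 else w[pref] <- cat_affinity
        sel <- cls == paste0("c", j)
        col[sel] <- sample(lv, sum(sel), replace = TRUE, prob = w)
      }
      out[[paste0("cat", f)]] <- col
    }
    df <- as.data.frame(out, stringsAsFactors = FALSE)
    if (missing_rate > 0) {
      cells <- length(df) * n_samples
      n_miss <- round(missing_rate * cells)
      hit <- sample.int(cells, n_miss)
      for (h in hit) {
        df[[((h - 1L) %/% n_samples) + 1L]][((h - 1L) %% n_samples) + 1L] <- NA
      }
    }
    df$class <- cls
    # shuffle rows so classes are interleaved like real exports
    df <- df[sample.int(n_samples), , drop = FALSE]
    rownames(df) <- NULL
    df
  })
}

# integer allocation of n into proportions: floor, then distribute the
# remainder to the largest fractional parts
#' @keywords internal
#' @noRd
largest_remainder <- function(props, n) {
  raw <- props * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Hand-built two-feature demonstration fixture
#'
#' A five-pattern, two-class toy in which the stored memory holds the
#' 6-bit strings directly (two 3-bit feature segments), together with the
#' intermediate quantities the classification of the query is expected to
#' produce: the similarity vector, the top-2 per-class scores, the one-hot
#' decision and the winning class. Useful for demonstrations and as a
#' ground-truth fixture in tests.
#'
#' @return A list with `raw` (the 5 x 2 real-valued patterns), `labels`,
#'   `bit_strings`, `profile`, `query_raw`, `query_bits`, `n`, and
#'   `expected` (z, scores, onehot, predicted, match_vectors).
#' @export
worked_example <- function() {
  list(
    raw = matrix(c(0.28, 0.17,
                   0.21, 0.09,
                   0.06, -0.15,
                   -0.24, 0.01,
                   0.07, -0.28),
                 ncol = 2L, byrow = TRUE,
                 dimnames = list(NULL, c("f1", "f2"))),
    labels = c("A", "A", "B", "B", "B"),
    bit_strings = c("101111", "111110", "010001", "000010", "110000"),
    profile = new_widths(c(3L, 3L), c("f1", "f2")),
    query_raw = c(0.16, 0.05),
    query_bits = "110010",
    n = 2L,
    expected = list(
      z = c(2L, 4L, 3L, 4L, 5L),
      scores = c(A = 6, B = 9),
      onehot = c(A = 0L, B = 1L),
      predicted = "B",
      match_vectors = c("100010", "110011", "011100", "001111", "111101")
    )
  )
}
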