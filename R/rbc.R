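#' Reflected-binary (Gray) code conversion
#'
#' `to_gray()` maps a nonnegative integer to its Gray-coded value by XORing
#' the number with itself shifted right by one bit; the most significant bit
#' is preserved. `from_gray()` inverts the mapping by a prefix-XOR scan.
#' Gray codes have the single-distance property: consecutive integers differ
#' in exactly one bit, so nearby numeric values stay nearby in Hamming space
#' after encoding.
#'
#' @param v,g Vector of nonnegative integers (doubles are accepted if whole).
#' @return Integer vector of the same length.
#' @examples
#' to_gray(5)              # 7, i.e. bits 111
#' from_gray(to_gray(0:31))
#' @export
to_gray <- function(v) {
  v <- check_nonneg_int(v, "v")
  bitwXor(v, bitwShiftR(v, 1L))
}

#' @rdname to_gray
#' @export
from_gray <- function(g) {
  g <- check_nonneg_int(g, "g")
  v <- g
  s <- bitwShiftR(g, 1L)
  while (any(s > 0L)) {
    v <- bitwXor(v, s)
    s <- bitwShiftR(s, 1L)
  }
  v
}

#' @keywords internal
#' @noRd
check_nonneg_int <- function(v, what) {
  if (!is.numeric(v) || any(!is.finite(v))) {
    stop(sprintf("`%s` must be finite and numeric", what), call. = FALSE)
  }
  if (any(v < 0)) stop(sprintf("`%s` must be nonnegative", what), call. = FALSE)
  if (any(v != floor(v))) {
    stop(sprintf("`%s` must be whole numbers", what), call. = FALSE)
  }
  as.integer(v)
}

# number of bits needed to represent x (>= 1 by convention, so an all-zero
# feature still occupies one bit position)
#' @keywords internal
#' @noRd
bit_length <- function(x) {
  x <- as.integer(x)
  n <- 0L
  while (x > 0L) {
    x <- bitwShiftR(x, 1L)
    n <- n + 1L
  }
  max(1L, n)
}

#' Expand integers to 0/1 bit rows, most significant bit first
#'
#' @param v Nonnegative integer vector.
#' @param width Bit width; each value must satisfy `v < 2^width`.
#' @return Integer matrix with `length(v)` rows and `width` columns.
#' @export
int_to_bits <- function(v, width) {
  v <- check_nonneg_int(v, "v")
  stopifnot(width >= 1L)
  if (any(v >= 2^width)) {
    stop(sprintf("value %d does not fit in %d bits",
                 max(v), as.integer(width)), call. = FALSE)
  }
  out <- matrix(0L, nrow = length(v), ncol = width)
  for (j in seq_len(width)) {
    out[, width - j + 1L] <- bitwAnd(bitwShiftR(v, j - 1L), 1L)
  }
  out
}

#' @rdname int_to_bits
#' @param bits Integer matrix (or vector) of 0/1 values, MSB first.
#' @export
bits_to_int <- function(bits) {
  if (is.vector(bits)) bits <- matrix(bits, nrow = 1L)
  w <- ncol(bits)
  as.integer(bits %*% 2^((w - 1L):0))
}

#' Convert between 0/1 bit rows and compact bit strings
#'
#' @param bits Integer 0/1 matrix or vector, MSB first.
#' @return `bits_to_string()` gives a character vector like `"110010"`;
#'   `string_to_bits()` gives the integer 0/1 matrix back.
#' @export
bits_to_string <- function(bits) {
  if (is.vector(bits)) bits <- matrix(bits, nrow = 1L)
  apply(bits, 1L, paste0, collapse = "")
}

#' @rdname bits_to_string
#' @param s Character vector of equal-length 0/1 strings.
#' @export
string_to_bits <- function(s) {
  lens <- nchar(s)
  if (length(unique(lens)) != 1L) {
    stop("bit strings must all have the same length", call. = FALSE)
  }
  bad <- grepl("[^01]", s)
  if (any(bad)) stop("bit strings may contain only 0 and 1", call. = FALSE)
  out <- matrix(0L, nrow = length(s), ncol = lens[1L])
  for (i in seq_along(s)) {
    out[i, ] <- as.integer(strsplit(s[i], "", fixed = TRUE)[[1L]])
  }
  out
}

#' Fit per-feature bit widths from an integer design matrix
#'
#' Each feature is allotted the number of bits needed for its largest
#' training value (at least one bit), and the features are laid out
#' left-to-right as contiguous bit segments of the concatenated pattern
#' string. Widths are fixed at fit time; queries are clipped to the
#' training range upstream so they always fit.
#'
#' @param x Matrix of nonnegative integers (rows = patterns).
#' @return An object of class `nsbc_widths` with elements `widths`,
#'   `offsets` (0-based segment starts), `total_bits` and `feature_names`.
#' @export
fit_widths <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) == 0L || ncol(x) == 0L) {
    stop("cannot fit bit widths on an empty matrix", call. = FALSE)
  }
  check_nonneg_int(as.vector(x), "x")
  widths <- vapply(seq_len(ncol(x)), function(j) bit_length(max(x[, j])), 1L)
  new_widths(widths, colnames(x))
}

#' @keywords internal
#' @noRd
new_widths <- function(widths, feature_names = NULL) {
  widths <- as.integer(widths)
  stopifnot(all(widths >= 1L))
  structure(
    list(
      widths = widths,
      offsets = c(0L, cumsum(widths)[-length(widths)]),
      total_bits = sum(widths),
      feature_names = feature_names %||% paste0("f", seq_along(widths))
    ),
    class = "nsbc_widths"
  )
}

#' @export
print.nsbc_widths <- function(x, ...) {
  cat("Bit-width profile:", length(x$widths), "features,",
      x$total_bits, "bits total\n")
  cat(paste0("  ", x$feature_names, ": ", x$widths, " bit(s)"), sep = "\n")
  invisible(x)
}

#' Gray-encode an integer matrix into concatenated bit patterns
#'
#' Every value is Gray-coded, zero-padded on the left to its feature's
#' fixed width, and the per-feature codes are concatenated in column order
#' into one bit string per row.
#'
#' @param x Matrix (or single row vector) of nonnegative integers.
#' @param profile An `nsbc_widths` object from [fit_widths()].
#' @param encoding `"gray"` (default) or `"binary"`; the latter is an
#'   ablation switch that skips the Gray step and stores plain fixed-width
#'   binary, useful for measuring what the single-distance property buys.
#' @return Integer 0/1 matrix with `profile$total_bits` columns.
#' @export
encode_matrix <- function(x, profile, encoding = c("gray", "binary")) {
  stopifnot(inherits(profile, "nsbc_widths"))
  encoding <- match.arg(encoding)
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != length(profile$widths)) {
    stop(sprintf("expected %d feature columns, got %d",
                 length(profile$widths), ncol(x)), call. = FALSE)
  }
  out <- matrix(0L, nrow = nrow(x), ncol = profile$total_bits)
  for (j in seq_len(ncol(x))) {
    w <- profile$widths[j]
    if (any(x[, j] >= 2^w)) {
      stop(sprintf("feature %d holds a value too large for its %d-bit width",
                   j, w), call. = FALSE)
    }
    v <- if (encoding == "gray") to_gray(x[, j]) else as.integer(x[, j])
    cols <- profile$offsets[j] + seq_len(w)
    out[, cols] <- int_to_bits(v, w)
  }
  out
}

#' @rdname encode_matrix
#' @param bits Integer 0/1 matrix as produced by `encode_matrix()`.
#' @return `decode_matrix()` returns the original integer matrix.
#' @export
decode_matrix <- function(bits, profile) {
  stopifnot(inherits(profile, "nsbc_widths"))
  if (is.vector(bits)) bits <- matrix(bits, nrow = 1L)
  if (ncol(bits) != profile$total_bits) {
    stop("bit matrix width does not match the profile", call. = FALSE)
  }
  out <- matrix(0L, nrow = nrow(bits), ncol = length(profile$widths))
  for (j in seq_along(profile$widths)) {
    cols <- profile$offsets[j] + seq_len(profile$widths[j])
    out[, j] <- from_gray(bits_to_int(bits[, cols, drop = FALSE]))
  }
  colnames(out) <- profile$feature_names
  out
}
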