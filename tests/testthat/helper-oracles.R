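# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# decimal truncation via string arithmetic: shift, print at high precision,
# cut the text at 2 decimals, scale by 100
truncate_scale_oracle <- function(v, min_shift) {
  vapply(v - min_shift, function(d) {
    s <- sprintf("%.9f", d)
    parts <- strsplit(s, ".", fixed = TRUE)[[1]]
    whole <- as.integer(parts[1])
    frac2 <- as.integer(substr(parts[2], 1, 2))
    if (d < 0 && (whole != 0 || frac2 != 0)) {
      # truncation toward -Inf for negatives (only reachable pre-clipping)
      -(abs(whole) * 100L + frac2) -
        as.integer(as.numeric(substr(parts[2], 3, 9)) > 0)
    } else {
      whole * 100L + frac2
    }
  }, integer(1))
}

# position-by-position bit comparison on 0/1 integer vectors
hamming_oracle <- function(a, b) {
  stopifnot(length(a) == length(b))
  sum(a != b)
}

# Gray code by the reflect-and-prefix construction (tabulated), independent
# of the XOR shortcut: the w-bit Gray sequence is the (w-1)-bit sequence
# followed by its reverse with a leading 1
gray_table_oracle <- function(w) {
  g <- c("0", "1")
  while (nchar(g[1]) < w) {
    g <- c(paste0("0", g), paste0("1", rev(g)))
  }
  g
}

# per-class top-n by explicit sort and sum
topn_oracle <- function(z, labels, n) {
  vapply(sort(unique(labels)), function(cls) {
    zi <- sort(z[labels == cls], decreasing = TRUE)
    sum(zi[seq_len(min(n, length(zi)))])
  }, numeric(1))
}

# per-row ranking by explicit sorting (rank 1 = largest value)
mean_ranks_oracle <- function(m) {
  r <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) {
    x <- m[i, ]
    for (j in seq_along(x)) {
      higher <- sum(x > x[j])
      tied <- sum(x == x[j])
      r[i, j] <- higher + (tied + 1) / 2
    }
  }
  colMeans(r)
}

rand_bits <- function(n, len) {
  matrix(sample(0:1, n * len, replace = TRUE), nrow = n)
}
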