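#' Friedman mean ranks of algorithms over datasets
#'
#' Within each dataset (row) the algorithms are ranked by descending score
#' — rank 1 is the best — with ties receiving the average of the tied rank
#' positions; the ranks are then averaged over datasets. The mean ranks of
#' `k` algorithms always sum to `k(k+1)/2`.
#'
#' @param results Numeric matrix or data.frame, datasets in rows and
#'   algorithms in columns, holding a score where larger is better (e.g.
#'   balanced accuracy). No missing cells allowed.
#' @return Named numeric vector of mean ranks.
#' @export
mean_ranks <- function(results) {
  m <- as_results_matrix(results)
  r <- t(apply(-m, 1L, rank, ties.method = "average"))
  colMeans(r)
}

#' @keywords internal
#' @noRd
as_results_matrix <- function(results) {
  m <- as.matrix(results)
  storage.mode(m) <- "double"
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop("need at least 2 datasets and 2 algorithms", call. = FALSE)
  }
  if (any(!is.finite(m))) {
    stop("the results matrix contains missing or non-finite cells",
         call. = FALSE)
  }
  if (is.null(colnames(m))) colnames(m) <- paste0("alg", seq_len(ncol(m)))
  m
}

#' Friedman rank test over a datasets-by-algorithms score matrix
#'
#' Computes the classic Friedman chi-square statistic
#' `12N/(k(k+1)) * sum(Rbar_j^2) - 3N(k+1)` on the column mean ranks
#' `Rbar_j`, with `k - 1` degrees of freedom, and its upper-tail p-value.
#'
#' @inheritParams mean_ranks
#' @return A list with `statistic`, `df`, `p_value` and `mean_ranks`.
#' @export
friedman_rank_test <- function(results) {
  m <- as_results_matrix(results)
  N <- nrow(m)
  k <- ncol(m)
  rbar <- mean_ranks(m)
  stat <- 12 * N / (k * (k + 1)) * sum(rbar^2) - 3 * N * (k + 1)
  list(
    statistic = stat,
    df = k - 1L,
    p_value = stats::pchisq(stat, df = k - 1L, lower.tail = FALSE),
    mean_ranks = rbar
  )
}

#' Holm step-down post-hoc comparisons against the best-ranked algorithm
#'
#' The control is the algorithm with the smallest (best) mean rank. Every
#' other algorithm is compared to it with
#' `z = (R_0 - R_i) / SE`, `SE = sqrt(k(k+1)/(6N))`, and a two-sided
#' normal p-value. Comparisons are sorted by decreasing `|z|` (equivalently
#' increasing p), and the i-th comparison in that order is tested against
#' the threshold `alpha / (m - i + 1)` with `m = k - 1`; the step-down
#' rule stops rejecting at the first non-significant comparison.
#'
#' @param ranks Named mean-rank vector from [mean_ranks()].
#' @param n_datasets Number of datasets `N` the ranks were averaged over.
#' @param alpha Family-wise significance level (default 0.05).
#' @param control Name of the control algorithm; defaults to the one with
#'   the smallest mean rank.
#' @return A data.frame, one row per comparison in test order, with
#'   columns `algorithm`, `mean_rank`, `z`, `p`, `holm` (threshold) and
#'   `reject`.
#' @export
holm_posthoc <- function(ranks, n_datasets, alpha = 0.05, control = NULL) {
  stopifnot(is.numeric(ranks), !is.null(names(ranks)))
  k <- length(ranks)
  N <- as.integer(n_datasets)
  if (k < 2L) stop("need at least two algorithms", call. = FALSE)
  if (N < 2L) stop("`n_datasets` must be at least 2", call. = FALSE)
  if (is.null(control)) control <- names(ranks)[which.min(ranks)]
  if (!control %in% names(ranks)) {
    stop(sprintf("unknown control algorithm '%s'", control), call. = FALSE)
  }
  se <- sqrt(k * (k + 1) / (6 * N))
  others <- setdiff(names(ranks), control)
  z <- (ranks[control] - ranks[others]) / se
  p <- 2 * stats::pnorm(-abs(z))
  ord <- order(abs(z), decreasing = TRUE)
  m <- length(others)
  out <- data.frame(
    algorithm = others[ord],
    mean_rank = unname(ranks[others][ord]),
    z = unname(z[ord]),
    p = unname(p[ord]),
    holm = alpha / (m - seq_len(m) + 1L),
    stringsAsFactors = FALSE
  )
  # step-down: reject while p <= threshold, stop at the first failure
  sig <- out$p <= out$holm
  first_fail <- match(FALSE, sig, nomatch = m + 1L)
  out$reject <- seq_len(m) < first_fail
  attr(out, "control") <- control
  attr(out, "se") <- se
  out
}
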