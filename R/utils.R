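# Internal helpers: seeded evaluation and named seed streams.

#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# One user-facing seed feeds independent named streams, so adding a new
# stochastic component never perturbs the draws of an existing one.
#' @keywords internal
#' @noRd
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  codes <- utf8ToInt(stream)
  h <- sum(codes * seq_along(codes) * 131)
  # doubles are exact here: all products stay far below 2^53
  as.integer((abs(seed) * 69069 + h * 40503 + 12345) %% 2147483629)
}

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
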