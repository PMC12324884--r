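#' Derive a reproducible child seed from a base seed and a key path
#'
#' All stochastic functions in the package take an explicit integer seed.
#' Nested components (replicates, grid cells, null ensembles) derive their own
#' seeds from the caller's seed plus a key path with a small multiplicative
#' congruential hash, so adding replicates or reordering runs never reshuffles
#' the streams of existing runs.
#'
#' @param base_seed integer base seed.
#' @param ... additional keys (integers or strings) identifying the child
#'   stream, hashed in order.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @examples
#' derive_seed(42, "replicate", 3)
#' @export
derive_seed <- function(base_seed, ...) {
  m <- 2147483647 # 2^31 - 1, prime
  x <- as.numeric(base_seed) %% m
  for (key in list(...)) {
    if (is.character(key)) {
      key <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)))
    }
    x <- (x * 69069 + as.numeric(key) + 1) %% m
  }
  as.integer(x %% (m - 2) + 1)
}

with_seed <- function(seed, expr) {
  set.seed(as.integer(seed))
  expr
}
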