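#' Derive a deterministic sub-stream seed
#'
#' Hashes a base seed together with a string tag into a 32-bit seed so every
#' operation (each k-means repeat, each simulated sample column, ...) draws
#' from its own reproducible stream. The same (seed, tag) pair always maps to
#' the same sub-seed, and the hash keeps sub-seeds below 2^31.
#'
#' @param seed integer base seed.
#' @param tag character tag naming the sub-stream.
#' @return a single integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  h <- as.numeric(seed) %% 2147483647
  for (code in utf8ToInt(as.character(tag)))
    h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

# Evaluate `expr` under a temporary RNG state seeded from (seed, tag).
with_stream <- function(seed, tag, expr) {
  withr::with_seed(derive_seed(seed, tag), expr)
}
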