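#' Derive a named substream seed from a base seed
#'
#' Deterministically maps a (base seed, stream id) pair to a 31-bit integer
#' seed, so that a single run seed can be fanned out to independent named
#' substreams (task, learning init, drift, perturbations, allocation) and
#' paired experiment arms can consume identical randomness.
#'
#' @param seed base integer seed.
#' @param id integer stream identifier.
#' @return a non-negative integer below 2^31.
#' @export
substream_seed <- function(seed, id) {
  s <- (as.double(seed) %% 2147483647) + 1
  i <- (as.double(id) %% 2147483647) + 1
  # two rounds of a Lehmer-style mix, kept in double-safe integer range
  x <- (s * 48271) %% 2147483647
  x <- (x + i * 16807) %% 2147483647
  x <- (x * 69621) %% 2147483647
  as.integer(x)
}
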