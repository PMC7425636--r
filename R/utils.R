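# Internal helpers shared across modules.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Derive a reproducible sub-seed for a named random substream
#'
#' All stochastic operations in the package draw from a single user seed;
#' independent stages (genome layout, state intervals, contact sampling,
#' synteny shuffling, permutations) use distinct named substreams so that
#' regenerating one stage does not perturb another.
#'
#' @param seed integer master seed.
#' @param stream character name of the substream.
#' @return an integer seed in [0, 2^31 - 2].
#' @export
substream_seed <- function(seed, stream) {
  codes <- utf8ToInt(stream)
  h <- sum(codes * seq_along(codes))
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483647)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == floor(x)
}
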