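#' Derive a named sub-seed from a root seed
#'
#' Splits one root seed into independent named streams (initialization,
#' dynamics, replicates, ...) so that subsystems can be replayed on their own.
#' Deterministic, and always inside the 32-bit integer range R's RNG accepts.
#'
#' @param root integer root seed.
#' @param stream stream name.
#' @param index optional replicate index within the stream.
#' @return an integer seed.
#' @export
derive_seed <- function(root, stream, index = 0L) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  val <- (as.numeric(root) * 48271 + h * 1009 + as.numeric(index) * 65537)
  as.integer(val %% 2147483647)
}

logit <- function(f) log(f / (1 - f))
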