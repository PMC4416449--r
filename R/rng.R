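#' Derive a child seed from a base seed and a tag
#'
#' The model uses several independent random streams (neuron placement,
#' connectivity wiring, synaptic weights, knockdown mask, sensor noise) so
#' that the initial-condition factorial of the knockdown experiments can vary
#' one source of randomness while holding the others fixed. Child seeds are
#' derived deterministically from a base seed and a small integer tag by a
#' multiplicative hash modulo a Mersenne prime, so every derived seed fits a
#' 32-bit signed integer.
#'
#' @param seed base seed (integer)
#' @param tag small integer distinguishing the stream
#' @return an integer seed in `[1, 2^31 - 2]`
#' @export
derive_seed <- function(seed, tag) {
  m <- 2147483647           # 2^31 - 1, prime
  s <- (as.numeric(seed) %% m) + 1
  t <- (as.numeric(tag) %% m) + 1
  # two rounds of multiplicative hashing, constants are arbitrary primes
  v <- (s * 48271) %% m
  v <- (v + t * 69621) %% m
  v <- (v * 16807) %% m
  as.integer(v %% (m - 1) + 1)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG state is untouched.
with_stream <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Truncated-normal draws by resampling (not clipping), so no probability mass
# accumulates at the interval bounds.
rnorm_trunc <- function(n, mean, sd, lower, upper) {
  out <- rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  while (length(bad) > 0L) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower | out[bad] > upper]
  }
  out
}
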