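# Small population configuration for fast unit tests; the acceptance tests
# build the full-size experimental network.
tiny_counts <- function() c(MF = 20L, GO = 5L, GC = 50L, BC = 10L, PC = 1L)

tiny_net <- function(placement = 1L, connectivity = 1L, weights = 1L,
                     counts = tiny_counts()) {
  build_hemisphere(counts, seeds = list(placement = placement,
                                        connectivity = connectivity,
                                        weights = weights))
}

tiny_model <- function(seed = 1L, counts = tiny_counts(), mirror = FALSE) {
  build_bicnn(counts, seeds = list(placement = derive_seed(seed, 1L),
                                   connectivity = derive_seed(seed, 1L),
                                   weights = derive_seed(seed, 2L)),
              mirror = mirror)
}

# Brute-force nearest-neighbour oracle: full pairwise distances, sorted.
nn_oracle <- function(targets, sources, fan_in) {
  out <- matrix(0L, nrow = targets$count, ncol = fan_in)
  for (i in seq_len(targets$count)) {
    d <- sqrt(colSums((t(sources$positions) - targets$positions[i, ])^2))
    out[i, ] <- order(d, seq_along(d))[seq_len(fan_in)]
  }
  out
}
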