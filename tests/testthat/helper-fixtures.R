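# Small fixtures shared across test files.

# A quick patch set: k classes, n patches, side px, 2 pseudo-stains.
quick_patchset <- function(n = 24, side = 16, k = 3, n_stains = 2,
                           separation = 1, noise_sd = 0.05, seed = 7) {
  generate_patch_dataset(synth_spec(k, n, side, n_stains = n_stains,
                                    separation = separation,
                                    noise_sd = noise_sd, seed = seed))
}

# A tiny network/config pair for fast model-level tests.
tiny_config <- function(n_clusters = 3, in_channels = 6, side = 8) {
  model_config(n_clusters, in_channels = in_channels, input_size = side,
               channel_plan = c(4L), upper_dim = 8L, classifier_hidden = 6L)
}

random_batch <- function(cfg, n = 4, seed = 5) {
  side <- cfg$input_size
  stainclust:::with_seed(seed,
    array(runif(side * side * cfg$in_channels * n),
          dim = c(side, side, cfg$in_channels, n)))
}

# Random row-stochastic matrix.
random_assignment <- function(n, k) {
  m <- matrix(stats::rexp(n * k), n, k)
  m / rowSums(m)
}
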