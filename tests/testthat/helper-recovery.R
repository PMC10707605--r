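# Shared state for the synthetic-recovery benchmark: one 4-class dataset
# (600 patches of 32 px, strongly separated) and memoized training runs so
# the recovery and model-selection checks reuse the same fits.

.recovery_cache <- new.env(parent = emptyenv())

recovery_dataset <- function() {
  if (is.null(.recovery_cache$dataset)) {
    .recovery_cache$dataset <-
      generate_patch_dataset(synth_spec(4, 600, 32, seed = 1))
  }
  .recovery_cache$dataset
}

recovery_fit <- function(n_clusters, seed) {
  key <- sprintf("fit_%d_%d", n_clusters, seed)
  if (is.null(.recovery_cache[[key]])) {
    .recovery_cache[[key]] <- train_imclust(
      recovery_dataset(),
      train_config(n_clusters, epochs = 300L, learning_rate = 1.0,
                   seed = seed))
  }
  .recovery_cache[[key]]
}
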