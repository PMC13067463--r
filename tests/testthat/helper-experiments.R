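# The hotspot recovery experiment feeds two acceptance properties
# (localization and the Bonferroni-vs-FDR ordering); run it once per
# session and cache the result.

.experiment_cache <- new.env(parent = emptyenv())

cached_hotspot_experiment <- function() {
  if (is.null(.experiment_cache$hotspot)) {
    .experiment_cache$hotspot <- hotspot_recovery_experiment(
      n_reps = 20, n_patients = 60, seed = 1)
  }
  .experiment_cache$hotspot
}
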