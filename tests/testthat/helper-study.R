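# The acceptance checks all consume one full-scale study (6 default networks
# with a task-transfer arm, 4 all-E-input networks), computed once per test
# session and cached here. Conditions are the study's standard ones: 400
# trials per category, dt = 0.01 tau, 1000-shuffle significance bounds, 50
# decoder splits.

.study_cache <- new.env(parent = emptyenv())

study_results <- function() {
  if (is.null(.study_cache$res)) {
    .study_cache$res <- suppressWarnings(
      run_study(seed = 101, n_default = 6, n_variant = 4)
    )
  }
  .study_cache$res
}
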