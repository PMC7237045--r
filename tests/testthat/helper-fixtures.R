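# small fixtures shared across test files; everything is generated in code

small_spec <- function(...) {
  network_spec(n_exc = 40L, n_inh = 10L, ...)
}

small_net <- function(seed = 1, ...) {
  build_network(small_spec(...), seed = seed)
}

quick_trials <- function(n_per = 4, n_pulses = c(8, 16), alphas = c(4, 2),
                         seed = 1) {
  trial_set(n_per, n_pulses = n_pulses, alphas = alphas, seed = seed)
}

# hand-built activity tensor wrapped as a rate_activity (trials x neurons x
# bins supplied as neurons x bins x trials array)
fake_activity <- function(rates, labels, bin_width = 1,
                          is_exc = NULL, input_mask = NULL) {
  n <- dim(rates)[1]
  structure(
    list(rates = rates,
         labels = factor(labels, levels = c("low", "high")),
         bin_width = bin_width, dt = 0.01,
         duration = dim(rates)[2] * bin_width,
         is_exc = is_exc %||% rep(c(TRUE, FALSE), length.out = n),
         input_mask = input_mask %||% rep(FALSE, n),
         downsampled = TRUE, trials = NULL),
    class = "rate_activity"
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# exhaustive pairwise-comparison AUC: the brute-force oracle
auc_brute <- function(low, high) {
  wins <- 0
  ties <- 0
  for (l in low) {
    for (h in high) {
      if (h > l) wins <- wins + 1
      if (h == l) ties <- ties + 1
    }
  }
  (wins + 0.5 * ties) / (length(low) * length(high))
}
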