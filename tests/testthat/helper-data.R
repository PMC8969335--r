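# Shared fixtures, all built in code at test time.

toy_count_table <- function() {
  feature_table(matrix(c(0, 5, 2, 0, 3, 1), nrow = 3, byrow = TRUE,
                       dimnames = list(c("S1", "S2", "S3"), c("F1", "F2"))))
}

small_binary_table <- function(n = 20L, d = 50L, seed = 7L) {
  set.seed(seed)
  feature_table(matrix(rbinom(n * d, 1, 0.3), n, d,
                       dimnames = list(paste0("S", seq_len(n)),
                                       paste0("F", seq_len(d)))))
}

# planted-feature synthetic dataset small enough for fast model fits
small_synth <- function(n_perturbed = 25L, d = 150L, seed = 1L,
                        likelihoods = c(0.1, 10)) {
  generate_dataset(
    generate_baseline(d, seed = seed + 1000L),
    perturbation_spec(n_perturbed = n_perturbed,
                      likelihood_choices = likelihoods),
    seed = seed)
}

fast_control <- function(...) {
  landmark_control(n_estimators = 8L, use_nnet = FALSE, ...)
}
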