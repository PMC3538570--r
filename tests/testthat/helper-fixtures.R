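# shared fixtures: the standard simulation conditions
truth_rates <- rate_params(0.4, 0.3, 0.2, 0.1)
truth_vec <- c(K1 = 0.4, k2 = 0.3, k3 = 0.2, k4 = 0.1)
feng_default <- feng_params()
ds_noiseless <- generate_dataset(truth_rates, alpha = 0)

# random strictly positive stable parameter draws for property tests
draw_rates <- function(n, seed = 42) {
  set.seed(seed)
  replicate(n, rate_params(runif(1, 0.1, 1.2), runif(1, 0.1, 0.8),
                           runif(1, 0.05, 0.5), runif(1, 0.02, 0.3)),
            simplify = FALSE)
}
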