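# small fixtures shared across test files; everything is generated in code

tiny_layout <- function() instrument_layout(3L, 3L, 2L)

tiny_params <- function(beta = 0.3, V = c(0.2, -0.1, 0.3, -0.4),
                        sigma = 0.1, delta = 1, alpha = 0.3) {
  structural_params(tiny_layout(),
                    alpha1 = alpha, alpha2 = alpha,
                    alpha31 = alpha, alpha32 = alpha,
                    beta1 = beta, beta2 = beta, delta = delta,
                    sigma_A = sigma, sigma_B = sigma, V = V)
}

tiny_combined <- function(n = 120, beta = 0.3, seed = 1, keep_truth = FALSE) {
  set.seed(seed)
  p <- tiny_params(beta = beta)
  combined_dataset(
    simulate_study(p, n / 2, "A", keep_truth = keep_truth),
    simulate_study(p, n / 2, "B", keep_truth = keep_truth))
}

fast_settings <- function(seed = 1, chains = 2L) {
  mcmc_settings(iter = 600L, warmup = 400L, chains = chains, seed = seed)
}
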