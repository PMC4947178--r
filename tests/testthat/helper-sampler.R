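# short chains for unit/property tests; defaults stay for the slow checks
quick_settings <- function(seed, iterations = 3000L, burn_in = 500L, ...) {
  sampler_settings(seed = seed, iterations = iterations, burn_in = burn_in,
                   ...)
}

# data drawn from the model itself: p_j ~ Beta(mean, v), x_j ~ Binom(n, p_j)
model_draw_dataset <- function(J, coverage, mean_rate, v_true, seed) {
  set.seed(seed)
  sh <- beta_shapes(mean_rate, v_true)
  pj <- rbeta(J, sh[["alpha"]], sh[["beta"]])
  x <- rbinom(J, coverage, pj)
  site_dataset("sim", 1L, "+",
               cell_counts(sprintf("c%d", seq_len(J)), x, rep(coverage, J)),
               bulk_counts(round(mean_rate * 1e4), 1e4))
}
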