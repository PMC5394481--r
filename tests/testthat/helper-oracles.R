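# Independent oracles used across the suite.

# Ma-Sandri-Sarkar recursion at full plating (eps = 1):
#   p_0 = e^-m,  p_n = (m/n) * sum_{k=0}^{n-1} p_k / (n - k + 1)
mss_pmf <- function(m, n_max) {
  p <- numeric(n_max + 1)
  p[1] <- exp(-m)
  for (n in seq_len(n_max)) {
    k <- 0:(n - 1)
    p[n + 1] <- m / n * sum(p[k + 1] / (n - k + 1))
  }
  p
}

# Monte-Carlo draw from the Lea-Coulson clone-size law (inverse CDF:
# P(S <= s) = 1 - 1/(s+1), so S = floor(1/U)), thinned binomially.
mc_thinned_clone <- function(n_draws, epsilon, cap = 1e7) {
  u <- runif(n_draws)
  s <- pmin(floor(1 / u), cap)
  rbinom(n_draws, size = s, prob = epsilon)
}

# Histogram of simulated mutant counts as probabilities over 0..n_max.
count_hist <- function(counts, n_max) {
  tabulate(pmin(counts, n_max + 1) + 1, nbins = n_max + 1) / length(counts)
}

# Binomial 3-standard-error band check, elementwise.
expect_within_3se <- function(obs_prob, exp_prob, n_draws) {
  se <- sqrt(pmax(exp_prob * (1 - exp_prob), 1e-12) / n_draws)
  expect_true(all(abs(obs_prob - exp_prob) <= 3 * se + 1e-12),
              label = paste0("max |obs-exp|/se = ",
                             round(max(abs(obs_prob - exp_prob) / se), 2)))
}
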