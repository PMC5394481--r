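test_that("MLE of m is zero on all-zero counts and matches a grid oracle", {
  e0 <- fluctuation_experiment("z", c(0, 0, 0, 0), epsilon = 0.5, n_t = 1e7)
  expect_identical(estimate_m(e0)$m_hat, 0)

  counts <- c(0, 1, 5, 0, 2, 0, 0, 0, 1, 0, 27, 0)
  e <- fluctuation_experiment("g", counts, epsilon = 1, n_t = 1e7)
  fit <- estimate_m(e)
  # exhaustive log-spaced grid search as the independent maximizer
  grid <- exp(seq(log(1e-4), log(50), length.out = 1e4))
  ll <- vapply(grid, function(m) ld_loglik(counts, m, epsilon = 1),
               numeric(1))
  best <- grid[which.max(ll)]
  step <- log(50 / 1e-4) / (1e4 - 1)
  expect_lt(abs(log(fit$m_hat) - log(best)), step)
  expect_gte(fit$loglik, max(ll))
})

test_that("MLE is scale-consistent under count doubling at matched m", {
  set.seed(11)
  cfg1 <- culture_sim_config(mu = 1e-6, generations = 20, epsilon = 1,
                             n_cultures = 500)
  m1 <- attr(simulate_cultures(cfg1), "truth")$m_true
  reps <- 40
  ratio <- replicate(reps, {
    s1 <- simulate_cultures(culture_sim_config(mu = 1e-6, generations = 20,
                                               n_cultures = 60))
    s2 <- simulate_cultures(culture_sim_config(mu = 2e-6, generations = 20,
                                               n_cultures = 60))
    estimate_m(s2)$m_hat / max(estimate_m(s1)$m_hat, 1e-9)
  })
  expect_lt(abs(median(ratio) - 2), 0.8)
  expect_gt(m1, 0)
})

test_that("profile CI solves the deviance equation at its endpoints", {
  set.seed(5)
  sim <- simulate_cultures(culture_sim_config(mu = 1e-6, generations = 20,
                                              epsilon = 0.7, n_cultures = 24))
  fit <- estimate_m(sim)
  ci <- profile_ci(sim, fit = fit)
  fns <- mutassay:::loglik_profile_fns(sim$counts, fit$clone)
  thr <- qchisq(0.95, 1)
  for (endpoint in ci) {
    expect_equal(2 * (fit$loglik - fns$ll(endpoint)), thr, tolerance = 1e-4)
  }
  expect_lt(ci[1], fit$m_hat)
  expect_gt(ci[2], fit$m_hat)
})

test_that("all-zero counts give the one-sided closed-form interval", {
  e0 <- fluctuation_experiment("z", rep(0, 24), epsilon = 1, n_t = 1e7)
  ci <- profile_ci(e0)
  expect_identical(ci[1], 0)
  expect_equal(ci[2], qchisq(0.95, 1) / (2 * 24), tolerance = 1e-10)
  # with partial plating the denominator shrinks by (1 - q0)
  e5 <- fluctuation_experiment("z", rep(0, 24), epsilon = 0.5, n_t = 1e7)
  q0 <- clone_size_pmf(0.5, 1)$q[1]
  expect_equal(profile_ci(e5)[2], qchisq(0.95, 1) / (2 * 24 * (1 - q0)),
               tolerance = 1e-9)
})

test_that("profile CI widens monotonically with the confidence level", {
  set.seed(8)
  sim <- simulate_cultures(culture_sim_config(mu = 1e-6, generations = 20,
                                              n_cultures = 24))
  fit <- estimate_m(sim)
  levels <- c(0.5, 0.8, 0.95, 0.99)
  cis <- vapply(levels, function(l) profile_ci(sim, level = l, fit = fit),
                numeric(2))
  expect_true(all(diff(cis[2, ]) > 0))
  expect_true(all(diff(cis[1, ]) < 0))
  expect_error(profile_ci(sim, level = 1.2), "level")
})

test_that("rate conversion divides m and CI by the CFU count", {
  r <- to_rate(4.4, c(2.6, 6.8), n_t = 2e7)
  expect_equal(r$rate, 2.2e-7)
  expect_equal(r$ci_low, 1.3e-7)
  expect_equal(r$ci_high, 3.4e-7)
  expect_equal(to_rate(0, c(0, 1), n_t = 5e6)$rate, 0)
  expect_error(to_rate(1, c(0.5, 2), n_t = 0), "n_t")
})

test_that("estimate_rate recovers a known rate within its own CI", {
  set.seed(303)
  mu <- 1e-6
  sim <- simulate_cultures(culture_sim_config(mu = mu, generations = 20,
                                              n_cultures = 48))
  r <- estimate_rate(sim)
  # truth uses divisions D = N_t - 1; the estimator divides by N_t
  expect_gt(mu, r$ci_low * 0.5)
  expect_lt(mu, r$ci_high * 2)
  expect_true(r$ci_low <= r$rate && r$rate <= r$ci_high)
})

test_that("LRT of an experiment against itself is exactly zero", {
  set.seed(21)
  sim <- simulate_cultures(culture_sim_config(mu = 1e-6, generations = 20,
                                              n_cultures = 24))
  cmp <- lrt_compare(sim, sim)
  expect_identical(cmp$lrt_stat, 0)
  expect_identical(cmp$p_raw, 1)
  expect_equal(cmp$fold, 1)
})

test_that("LRT handles degenerate and strongly separated experiments", {
  z <- fluctuation_experiment("z1", rep(0, 12), epsilon = 1, n_t = 1e6)
  z2 <- fluctuation_experiment("z2", rep(0, 12), epsilon = 1, n_t = 1e6)
  cmp0 <- lrt_compare(z, z2)
  expect_identical(cmp0$lrt_stat, 0)
  expect_identical(cmp0$p_raw, 1)

  set.seed(99)
  lowr <- simulate_cultures(culture_sim_config(mu = 2e-9, generations = 20,
                                               n_cultures = 24))
  high <- simulate_cultures(culture_sim_config(mu = 1e-5, generations = 20,
                                               n_cultures = 24))
  cmp <- lrt_compare(high, lowr)
  expect_gt(cmp$lrt_stat, qchisq(0.95, 1))
  expect_lt(cmp$p_raw, 1e-4)
  expect_gt(cmp$fold, 100)
})

test_that("LRT allows different plating efficiencies and CFU per arm", {
  set.seed(13)
  a <- simulate_cultures(culture_sim_config(mu = 1e-6, generations = 20,
                                            epsilon = 0.4, n_cultures = 24))
  b <- simulate_cultures(culture_sim_config(mu = 1e-6, generations = 18,
                                            epsilon = 1, n_cultures = 24))
  cmp <- lrt_compare(a, b)
  expect_gte(cmp$lrt_stat, 0)
  expect_true(cmp$p_raw >= 0 && cmp$p_raw <= 1)
})

test_that("Bonferroni correction scales by family size and caps at one", {
  expect_equal(bonferroni(0.01), 0.01)
  expect_equal(bonferroni(c(0.01, 0.02, 0.4)), c(0.03, 0.06, 1.0))
  expect_equal(bonferroni(c(0, 1)), c(0, 1))
  expect_error(bonferroni(c(0.5, 1.2)), "0, 1")
})

test_that("fold effects reproduce the published worked examples", {
  expect_equal(eex_effect(6.8, 180)$rounded, 0.04)
  expect_equal(eex_effect(160, 2700)$rounded, 0.06)
  expect_equal(eex_effect(3.7, 3.7)$fold, 1)
  expect_error(eex_effect(1, 0), "rate_control")
})
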