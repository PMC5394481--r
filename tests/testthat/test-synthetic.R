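test_that("culture simulator honours degenerate and seeded configs", {
  cfg0 <- culture_sim_config(mu = 0, n_cultures = 50, seed = 1)
  expect_true(all(simulate_cultures(cfg0)$counts == 0))
  cfg <- culture_sim_config(mu = 1e-6, n_cultures = 200, seed = 42)
  a <- simulate_cultures(cfg)
  b <- simulate_cultures(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(attr(a, "truth"), attr(b, "truth"))
  expect_error(culture_sim_config(mu = -1), "mu")
})

test_that("zero-count fraction matches exp(-m_true) at full plating", {
  set.seed(314)
  cfg <- culture_sim_config(mu = 1e-6, n0 = 1, generations = 20,
                            epsilon = 1, n_cultures = 1e5)
  sim <- simulate_cultures(cfg)
  m_true <- attr(sim, "truth")$m_true
  expect_equal(m_true, 1e-6 * (2^20 - 1))
  p0 <- exp(-m_true)
  obs <- mean(sim$counts == 0)
  se <- sqrt(p0 * (1 - p0) / cfg$n_cultures)
  expect_lt(abs(obs - p0), 3 * se)
})

test_that("zero-count fraction under partial plating uses 1 - q0", {
  set.seed(2718)
  cfg <- culture_sim_config(mu = 2e-6, generations = 19, epsilon = 0.3,
                            n_cultures = 4e4)
  sim <- simulate_cultures(cfg)
  m_true <- attr(sim, "truth")$m_true
  q0 <- clone_size_pmf(0.3, 1)$q[1]
  p0 <- exp(-m_true * (1 - q0))
  se <- sqrt(p0 * (1 - p0) / cfg$n_cultures)
  expect_lt(abs(mean(sim$counts == 0) - p0), 3 * se)
})

test_that("variant-table generator is deterministic and truth-labelled", {
  cfg <- spectrum_sim_config(genome_length = 1e5, seed = 7,
                             class_rates = c("C>T/G>A" = 5e-4,
                                             "C>A/G>T" = 2e-4,
                                             "C>G/G>C" = 5e-5,
                                             "A>G/T>C" = 3e-4,
                                             "A>C/T>G" = 5e-5,
                                             "A>T/T>A" = 5e-5,
                                             insertion = 2e-5,
                                             deletion = 2e-5))
  t1 <- simulate_variant_table(cfg)
  t2 <- simulate_variant_table(cfg)
  expect_identical(t1$variants, t2$variants)
  expect_identical(t1$truth, t2$truth)
  expect_true(all(c("class_counts", "n_snp_decoys", "n_mask_decoys") %in%
                  names(t1$truth)))
  # empty configuration gives only decoy records
  cfg0 <- spectrum_sim_config(genome_length = 5e4, seed = 1,
                              class_rates = setNames(rep(0, 8),
                                                     mutation_classes()),
                              n_snp_decoys = 0, n_mask_decoys = 0)
  expect_identical(nrow(simulate_variant_table(cfg0)$variants), 0L)
})

test_that("expected planted mutations follow the rate x eligible-sites law", {
  # C>T/G>A at rate r on the unmasked C+G sites: Poisson with that mean
  rate <- 2e-5
  lams <- obs <- numeric(30)
  for (s in seq_len(30)) {
    cfg <- spectrum_sim_config(
      genome_length = 1e6,
      base_fractions = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3),
      class_rates = c("C>T/G>A" = rate, "C>A/G>T" = 0, "C>G/G>C" = 0,
                      "A>G/T>C" = 0, "A>C/T>G" = 0, "A>T/T>A" = 0,
                      insertion = 0, deletion = 0),
      mask_fraction = 0, n_snp_decoys = 0, n_mask_decoys = 0, seed = s)
    tab <- simulate_variant_table(cfg)
    lams[s] <- rate * (tab$composition$n_C + tab$composition$n_G)
    obs[s] <- tab$truth$class_counts[["C>T/G>A"]]
  }
  lambda <- mean(lams)      # ~ 2e-5 * 4e5 = 8 per genome
  expect_equal(lambda, 8, tolerance = 0.05)
  se <- sqrt(lambda / 30)
  expect_lt(abs(mean(obs) - lambda), 3 * se)
})

test_that("noiseless tables round-trip exactly through filter + classify", {
  cfg <- spectrum_sim_config(genome_length = 2e5, depth_mean = 100,
                             vaf_noise = FALSE, seed = 12,
                             class_rates = c("C>T/G>A" = 6e-4,
                                             "C>A/G>T" = 3e-4,
                                             "C>G/G>C" = 1e-4,
                                             "A>G/T>C" = 4e-4,
                                             "A>C/T>G" = 1e-4,
                                             "A>T/T>A" = 1e-4,
                                             insertion = 5e-5,
                                             deletion = 5e-5))
  tab <- simulate_variant_table(cfg)
  flt <- filter_variants(tab$variants, masks = tab$masks,
                         strain_snps = tab$strain_snps)
  ss <- spectrum_summary(flt, comp = tab$composition)
  expect_equal(unname(ss$counts[mutation_classes()]),
               unname(tab$truth$class_counts[mutation_classes()]))
  # decoys were removed, not silently passed
  expect_equal(sum(flt$flag == "strain_snp"), tab$truth$n_snp_decoys)
  expect_equal(sum(flt$flag == "masked"), tab$truth$n_mask_decoys)
})

test_that("fixture bundle is byte-stable and parses under standard readers", {
  d1 <- file.path(tempdir(), "bundle_a")
  d2 <- file.path(tempdir(), "bundle_b")
  unlink(c(d1, d2), recursive = TRUE)
  p1 <- write_fixture_bundle(d1, seed = 5, genome_length = 2e4,
                             n_isolates = 2)
  p2 <- write_fixture_bundle(d2, seed = 5, genome_length = 2e4,
                             n_isolates = 2)
  for (nm in names(p1)) {
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]),
                     label = paste("bundle file", nm))
  }
  # VCF parses under a standard VCF reader
  v <- vcfR::read.vcfR(p1$vcf_mutator_1, verbose = FALSE)
  expect_gt(nrow(v@fix), 0)
  # end-to-end: read the bundle back and recover the recorded truth
  inputs <- read_variants(p1$vcf_mutator_1, snp_path = p1$snps,
                          bed_path = p1$bed, fasta_path = p1$fasta)
  flt <- filter_variants(inputs$variants, masks = inputs$masks,
                         strain_snps = inputs$strain_snps)
  truth <- jsonlite::read_json(p1$truth)
  truth_counts <- unlist(truth$spectra$mutator_1$class_counts)
  ss <- spectrum_summary(flt, comp = inputs$composition)
  # read noise moves some VAFs outside [0.4, 0.6]; recovered counts can
  # only fall short of planted truth, never exceed it
  expect_true(all(ss$counts[names(truth_counts)] <= truth_counts))
  expect_gt(sum(ss$counts), 0.8 * sum(truth_counts))
})
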