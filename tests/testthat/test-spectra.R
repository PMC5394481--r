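test_that("substitutions collapse to pyrimidine-anchored pair labels", {
  expect_equal(classify_mutation("G", "A"), "C>T/G>A")
  expect_equal(classify_mutation("C", "T"), "C>T/G>A")
  expect_equal(classify_mutation("A", "AT"), "insertion")
  expect_equal(classify_mutation("CA", "C"), "deletion")
  # strand involution across all 12 single-base changes
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (r in names(comp)) {
    for (a in setdiff(names(comp), r)) {
      expect_equal(classify_mutation(r, a),
                   classify_mutation(comp[[r]], comp[[a]]),
                   label = paste(r, ">", a))
    }
  }
  expect_error(classify_mutation("N", "A"), "A, C, G, T")
  expect_error(classify_mutation("A", "A"), "differ")
  expect_warning(out <- classify_mutation("AC", "GT"), "not supported")
  expect_equal(out, "unsupported")
})

test_that("variant filtering applies the flags in precedence order", {
  rec <- data.frame(
    chrom = "chrS",
    pos = c(100, 200, 300, 1500, 1600, 400),
    ref = "C", alt = "T",
    depth = c(15, 100, 100, 100, 10, 21),
    alt_frac = c(0.50, 0.50, 0.35, 0.50, 0.30, 0.40))
  masks <- data.frame(chrom = "chrS", start = 1000, end = 2000)
  snps <- data.frame(chrom = "chrS", pos = 400)
  out <- filter_variants(rec, min_depth = 20, masks = masks,
                         strain_snps = snps)
  expect_equal(out$flag, c("low_coverage", "pass", "vaf_out_of_range",
                           "masked", "low_coverage", "strain_snp"))
  # depth threshold is strict: >20-fold passes, exactly 20 does not
  rec20 <- data.frame(chrom = "c", pos = 1, ref = "C", alt = "T",
                      depth = c(20, 21), alt_frac = 0.5)
  expect_equal(filter_variants(rec20)$flag, c("low_coverage", "pass"))
  # VAF bounds are inclusive
  recv <- data.frame(chrom = "c", pos = 1, ref = "C", alt = "T",
                     depth = 100, alt_frac = c(0.40, 0.60, 0.399, 0.601))
  expect_equal(filter_variants(recv)$flag,
               c("pass", "pass", "vaf_out_of_range", "vaf_out_of_range"))
})

test_that("filtering is idempotent and invariant to record order", {
  set.seed(77)
  rec <- data.frame(
    chrom = "chrS", pos = sample.int(5000, 300),
    ref = "G", alt = "A",
    depth = rpois(300, 40),
    alt_frac = runif(300))
  masks <- data.frame(chrom = "chrS", start = c(0, 2500), end = c(500, 3000))
  once <- filter_variants(rec, masks = masks)
  twice <- filter_variants(once, masks = masks)
  expect_identical(once$flag, twice$flag)
  perm <- sample.int(nrow(rec))
  shuffled <- filter_variants(rec[perm, ], masks = masks)
  expect_identical(shuffled$flag, once$flag[perm])
  expect_identical(sum(shuffled$flag == "pass"), sum(once$flag == "pass"))
  expect_error(
    filter_variants(rec, masks = data.frame(chrom = "chrS", start = 10,
                                            end = 10)),
    "end <= start")
})

test_that("mask intervals follow BED half-open 0-based convention", {
  rec <- data.frame(chrom = "c", pos = c(10, 11, 20, 21),
                    ref = "C", alt = "T", depth = 100, alt_frac = 0.5)
  # BED [10, 20) covers 1-based positions 11..20
  masks <- data.frame(chrom = "c", start = 10, end = 20)
  out <- filter_variants(rec, masks = masks)
  expect_equal(out$flag, c("pass", "masked", "masked", "pass"))
})

test_that("class frequencies use the base-specific denominators", {
  comp <- genome_composition(3e5, 5e5, 5e5, 3e5,
                             total_scored = 1.6e6, total_sequenced = 2e6)
  fr <- class_frequencies(c("C>T/G>A" = 10), comp)
  expect_equal(unname(fr["C>T/G>A"]), 10 / 1e6)
  expect_equal(unname(fr["A>G/T>C"]), 0)
  fr2 <- class_frequencies(c("A>T/T>A" = 6, insertion = 4, deletion = 8),
                           comp)
  expect_equal(unname(fr2["A>T/T>A"]), 6 / 6e5)
  expect_equal(unname(fr2["insertion"]), 4 / 1.6e6)
  fr3 <- class_frequencies(c(insertion = 4), comp,
                           indel_denominator = "sequenced")
  expect_equal(unname(fr3["insertion"]), 4 / 2e6)
  expect_true(all(class_frequencies(setNames(numeric(0), character(0)),
                                    comp) == 0))
  # doubling composition and counts leaves frequencies unchanged
  comp2 <- genome_composition(6e5, 1e6, 1e6, 6e5,
                              total_scored = 3.2e6, total_sequenced = 4e6)
  expect_equal(class_frequencies(c("C>T/G>A" = 20), comp2),
               class_frequencies(c("C>T/G>A" = 10), comp))
  empty <- genome_composition(0, 0, 0, 0)
  expect_error(class_frequencies(c("C>T/G>A" = 1), empty), "denominator")
})

test_that("class fractions normalize to one and flag empty spectra", {
  fx <- class_fractions(c("C>T/G>A" = 1, "A>G/T>C" = 1))
  expect_equal(unname(fx[c("C>T/G>A", "A>G/T>C")]), c(0.5, 0.5))
  fy <- class_fractions(c("C>T/G>A" = 3, "C>A/G>T" = 0, insertion = 1))
  expect_equal(unname(fy[c("C>T/G>A", "C>A/G>T", "insertion")]),
               c(0.75, 0, 0.25))
  expect_equal(sum(fy), 1)
  fz <- class_fractions(c("C>T/G>A" = 0))
  expect_true(all(fz == 0))
  expect_true(isTRUE(attr(fz, "empty")))
})

test_that("colony sizes map to generations by ceiling log2", {
  expect_identical(generations_from_cells(1e6), 20L)
  expect_identical(generations_from_cells(1e5), 17L)
  expect_identical(generations_from_cells(1024), 10L)
  expect_identical(generations_from_cells(1), 0L)
  expect_error(generations_from_cells(0), "n_cells")
})

test_that("genome-wide per-division rate is mutations over generations", {
  expect_equal(genome_wide_rate(1780, 20), 89)
  expect_equal(genome_wide_rate(0, 20), 0)
  expect_equal(genome_wide_rate(566, 20), 28.3)
  expect_error(genome_wide_rate(10, 0), "generations")
})

test_that("group summaries average isolates and report sample SD", {
  comp <- genome_composition(2.5e5, 2.5e5, 2.5e5, 2.5e5)
  s1 <- spectrum_summary(counts = c("C>T/G>A" = 5), comp = comp)
  s2 <- spectrum_summary(counts = c("C>T/G>A" = 15), comp = comp)
  g <- summarize_group(list(s1, s2))
  expect_equal(unname(g$counts["C>T/G>A"]), 20)
  expect_equal(unname(g$freq_mean["C>T/G>A"]), 10 / 5e5)
  expect_equal(unname(g$freq_sd["C>T/G>A"]), sd(c(5, 15) / 5e5))
  # frequencies 1e-5 and 3e-5: mean 2e-5, sd = sqrt(2)*1e-5
  sa <- spectrum_summary(counts = c("A>G/T>C" = 5), comp = comp)
  sb <- spectrum_summary(counts = c("A>G/T>C" = 15), comp = comp)
  gg <- summarize_group(list(sa, sb))
  expect_equal(unname(gg$freq_mean["A>G/T>C"]), 2e-5)
  expect_equal(unname(gg$freq_sd["A>G/T>C"]), 1.414214e-5, tolerance = 1e-6)
  # identical isolates have zero SD; single isolate flagged with SD 0
  gsame <- summarize_group(list(s1, s1))
  expect_true(all(gsame$freq_sd == 0) && all(gsame$frac_sd == 0))
  gone <- summarize_group(list(s1))
  expect_true(gone$single_isolate)
  expect_true(all(gone$freq_sd == 0))
  expect_error(summarize_group(list()), "at least 1")
})
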