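#' Configuration for simulated fluctuation cultures
#'
#' @param mu Mutation rate per cell division (>= 0).
#' @param n0 Inoculum cells (>= 1).
#' @param generations Integer doublings of growth (>= 1).
#' @param epsilon Plating efficiency in (0, 1].
#' @param n_cultures Number of replica cultures (>= 1).
#' @param seed Optional RNG seed (integer); when supplied, the global RNG
#'   is seeded so a fixed configuration reproduces its output exactly.
#' @return Object of class `culture_sim_config`.
#' @export
culture_sim_config <- function(mu, n0 = 1, generations = 20, epsilon = 1,
                               n_cultures = 24, seed = NULL) {
  stopifnot(mu >= 0, mu <= 1, n0 >= 1, generations >= 1,
            epsilon > 0, epsilon <= 1, n_cultures >= 1)
  structure(list(mu = mu, n0 = n0, generations = as.integer(generations),
                 epsilon = epsilon, n_cultures = as.integer(n_cultures),
                 seed = seed),
            class = "culture_sim_config")
}

#' Simulate replica fluctuation cultures
#'
#' Exact stochastic simulation of the classical fluctuation-assay model for
#' a culture growing asynchronously (exponentially) from `n0` to
#' \eqn{N_t = n_0 2^{generations}} cells. Each of the \eqn{D = N_t - n_0}
#' wild-type cell divisions produces a mutant daughter with probability
#' `mu`; mutants breed true with wild-type fitness. A mutant clone founded
#' when the population has n cells grows to a final size that is
#' Geometric with mean \eqn{N_t/n} (the clone-size law of a lineage in an
#' asynchronous exponentially growing population); integrating over the
#' uniformly distributed founding division recovers the Lea-Coulson
#' clone-size law \eqn{P(S=s) = 1/(s(s+1))}. Each mutant cell is then
#' plated independently with probability `epsilon` and the observed count
#' is the number of plated mutant cells.
#'
#' The generative path (binomial mutation seeding, geometric clone growth,
#' binomial plating) is independent of the analytic pmf recursion in
#' [ld_pmf()], so the simulator serves as an oracle for it.
#'
#' @param config A [culture_sim_config()].
#' @return A [fluctuation_experiment()] whose `counts` are the simulated
#'   colony counts, with attribute `truth`: a list holding `m_true`
#'   (`mu * D`, the expected mutational events per culture), `mu`,
#'   `divisions` and `n_t`.
#' @export
simulate_cultures <- function(config) {
  stopifnot(inherits(config, "culture_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n_t <- config$n0 * 2^config$generations
  D <- n_t - config$n0
  m_true <- config$mu * D

  k <- if (D <= .Machine$integer.max) {
    rbinom(config$n_cultures, size = D, prob = config$mu)
  } else {
    # binomial with > 2^31 trials and tiny mu: Poisson limit
    rpois(config$n_cultures, lambda = m_true)
  }
  counts <- integer(config$n_cultures)
  total <- sum(k)
  if (total > 0) {
    culture <- rep.int(seq_len(config$n_cultures), k)
    idx <- floor(runif(total) * D) + 1          # founding division, uniform
    u <- (config$n0 + idx) / n_t                # founding population fraction
    clone <- rgeom(total, prob = u) + 1         # clone final size, mean 1/u
    plated <- if (config$epsilon < 1) {
      rbinom(total, size = clone, prob = config$epsilon)
    } else clone
    agg <- rowsum(plated, culture)
    counts[as.integer(rownames(agg))] <- agg
  }

  exp_out <- fluctuation_experiment(
    strain = sprintf("sim_mu%.3g", config$mu),
    counts = counts, epsilon = config$epsilon, n_t = n_t)
  attr(exp_out, "truth") <- list(m_true = m_true, mu = config$mu,
                                 divisions = D, n_t = n_t)
  exp_out
}

#' Configuration for a simulated mutation-accumulation variant table
#'
#' Defaults emulate the study system: a diploid yeast-scale genome
#' (12 Mb, 38% GC), sequencing depth in the 100-300x range, heterozygous
#' variants with read-sampling noise around an allele fraction of 0.5, a
#' few percent of the genome masked as low-complexity, and per-class
#' mutation rates calibrated so one ultramutator-heterozygote genome
#' accumulates on the order of 1.8e3 mutations (~20 generations of growth),
#' dominated by C>T/G>A transitions, with A>G/T>C transitions and C>A/G>T
#' transversions at roughly half that frequency.
#'
#' @param genome_length Bases in the synthetic genome.
#' @param base_fractions Named A/C/G/T composition summing to 1.
#' @param class_rates Named per-class mutations per eligible base per
#'   colony (names from [mutation_classes()]).
#' @param depth_mean Mean sequencing depth (Poisson).
#' @param vaf_noise Logical; if TRUE alternate reads are
#'   Binomial(depth, 0.5), else `alt_frac` is exactly 0.5.
#' @param mask_fraction Fraction of the genome masked as low-complexity.
#' @param n_snp_decoys Strain-background SNP decoy records planted in the
#'   variant table (and listed in the SNP site set).
#' @param n_mask_decoys Variant decoys planted inside masked regions.
#' @param seed Optional RNG seed.
#' @return Object of class `spectrum_sim_config`.
#' @export
spectrum_sim_config <- function(genome_length = 12e6,
                                base_fractions = c(A = 0.31, C = 0.19,
                                                   G = 0.19, T = 0.31),
                                class_rates = c("C>T/G>A" = 1.55e-4,
                                                "C>A/G>T" = 7.7e-5,
                                                "C>G/G>C" = 1.3e-5,
                                                "A>G/T>C" = 5.1e-5,
                                                "A>C/T>G" = 1.2e-5,
                                                "A>T/T>A" = 1.1e-5,
                                                insertion = 3.5e-6,
                                                deletion = 7e-6),
                                depth_mean = 200, vaf_noise = TRUE,
                                mask_fraction = 0.04,
                                n_snp_decoys = 25, n_mask_decoys = 25,
                                seed = NULL) {
  stopifnot(genome_length >= 1000,
            length(base_fractions) == 4,
            abs(sum(base_fractions) - 1) < 1e-8,
            all(base_fractions > 0),
            all(class_rates >= 0),
            depth_mean > 0, mask_fraction >= 0, mask_fraction < 1,
            n_snp_decoys >= 0, n_mask_decoys >= 0)
  names(base_fractions) <- toupper(names(base_fractions))
  class_rates <- normalize_class_counts(class_rates)  # reuse name checks
  structure(list(genome_length = as.integer(genome_length),
                 base_fractions = base_fractions[c("A", "C", "G", "T")],
                 class_rates = class_rates,
                 depth_mean = depth_mean, vaf_noise = isTRUE(vaf_noise),
                 mask_fraction = mask_fraction,
                 n_snp_decoys = as.integer(n_snp_decoys),
                 n_mask_decoys = as.integer(n_mask_decoys),
                 seed = seed),
            class = "spectrum_sim_config")
}

#' Simulate a heterozygous diploid variant table with ground truth
#'
#' Draws per-class mutation counts as Poisson with mean
#' `class_rate * eligible bases` (eligible = unmasked sites carrying a base
#' that can produce the class), places them uniformly over eligible sites,
#' and emits heterozygous records with `depth ~ Poisson(depth_mean)` and
#' alternate reads `~ Binomial(depth, 0.5)` when `vaf_noise` is on. A
#' configurable number of strain-SNP and masked decoy records are planted
#' for the filter to remove. The ground truth (planted per-class counts)
#' always accompanies the output.
#'
#' @param config A [spectrum_sim_config()].
#' @return List with `variants` (data frame: chrom, pos, ref, alt, depth,
#'   alt_frac), `composition` (a [genome_composition()] over unmasked
#'   sites), `masks` (0-based half-open data frame), `strain_snps`
#'   (chrom/pos data frame), `genome` (integer base codes 1-4 = A/C/G/T),
#'   `truth` (list: `class_counts`, decoy counts) and `config`.
#' @export
simulate_variant_table <- function(config) {
  stopifnot(inherits(config, "spectrum_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  L <- config$genome_length
  bases <- c("A", "C", "G", "T")
  genome <- sample.int(4L, L, replace = TRUE, prob = config$base_fractions)

  # masked low-complexity regions: whole 1-kb windows
  win <- 1000L
  n_win <- L %/% win
  n_masked_win <- round(n_win * config$mask_fraction)
  masked_win <- sort(sample.int(n_win, n_masked_win))
  masks <- data.frame(chrom = rep("chrS", n_masked_win),
                      start = (masked_win - 1L) * win,   # 0-based
                      end = masked_win * win,
                      stringsAsFactors = FALSE)
  masked_site <- rep(FALSE, L)
  for (w in masked_win) masked_site[((w - 1L) * win + 1L):(w * win)] <- TRUE

  base_counts <- tabulate(genome[!masked_site], nbins = 4L)
  names(base_counts) <- bases
  comp <- genome_composition(unname(base_counts["A"]), unname(base_counts["C"]),
                             unname(base_counts["G"]), unname(base_counts["T"]),
                             total_scored = sum(base_counts),
                             total_sequenced = L)

  cg_sites <- which(!masked_site & (genome == 2L | genome == 3L))
  at_sites <- which(!masked_site & (genome == 1L | genome == 4L))
  all_sites <- which(!masked_site)

  eligible <- function(class) {
    switch(substr(class, 1, 1),
           C = cg_sites,
           A = at_sites,
           i = all_sites, d = all_sites)
  }
  # alt allele for a substitution class at a given ref base: the class label
  # "X>Y/Xc>Yc" names the change at the pyrimidine-anchored strand; a site
  # carrying the complementary base mutates to the complementary target.
  class_alt <- function(class, ref_base) {
    anc <- substr(class, 1, 1); to <- substr(class, 3, 3)
    ifelse(ref_base == anc, to, COMPLEMENT[to])
  }

  rec <- list()
  true_counts <- setNames(numeric(8), mutation_classes())
  used <- logical(L)
  for (cl in mutation_classes()) {
    sites <- eligible(cl)
    lambda <- config$class_rates[cl] * length(sites)
    if (lambda > length(sites) / 2) {
      stop("class rate for ", cl, " implies more mutations than eligible ",
           "sites", call. = FALSE)
    }
    n_cl <- rpois(1, lambda)
    if (n_cl == 0) { true_counts[cl] <- 0; next }
    pos <- sample(sites, n_cl)
    pos <- pos[!used[pos]]
    used[pos] <- TRUE
    n_cl <- length(pos)
    true_counts[cl] <- n_cl
    if (n_cl == 0) next
    rb <- bases[genome[pos]]
    if (cl == "insertion") {
      ref <- rb
      alt <- paste0(rb, bases[sample.int(4L, n_cl, replace = TRUE)])
    } else if (cl == "deletion") {
      pos <- pmin(pos, L - 1L)
      ref <- paste0(bases[genome[pos]], bases[genome[pos + 1L]])
      alt <- bases[genome[pos]]
    } else {
      ref <- rb
      alt <- unname(class_alt(cl, rb))
    }
    rec[[cl]] <- data.frame(pos = pos, ref = ref, alt = alt,
                            stringsAsFactors = FALSE)
  }

  # decoys: strain-background SNPs (unmasked) and variants inside masks
  snp_df <- data.frame(chrom = character(0), pos = integer(0))
  if (config$n_snp_decoys > 0) {
    free <- all_sites[!used[all_sites]]
    spos <- sample(free, min(config$n_snp_decoys, length(free)))
    used[spos] <- TRUE
    rb <- bases[genome[spos]]
    alt <- vapply(rb, function(b) sample(setdiff(bases, b), 1), character(1))
    rec[["snp_decoy"]] <- data.frame(pos = spos, ref = rb, alt = unname(alt),
                                     stringsAsFactors = FALSE)
    snp_df <- data.frame(chrom = rep("chrS", length(spos)), pos = spos)
  }
  n_mask_planted <- 0L
  if (config$n_mask_decoys > 0 && any(masked_site)) {
    mpos <- sample(which(masked_site), config$n_mask_decoys)
    rb <- bases[genome[mpos]]
    alt <- vapply(rb, function(b) sample(setdiff(bases, b), 1), character(1))
    rec[["mask_decoy"]] <- data.frame(pos = mpos, ref = rb, alt = unname(alt),
                                      stringsAsFactors = FALSE)
    n_mask_planted <- length(mpos)
  }

  variants <- do.call(rbind, rec)
  if (is.null(variants)) {
    variants <- data.frame(pos = integer(0), ref = character(0),
                           alt = character(0))
  }
  n <- nrow(variants)
  depth <- pmax(1L, rpois(n, config$depth_mean))
  alt_frac <- if (config$vaf_noise) rbinom(n, depth, 0.5) / depth else
    rep(0.5, n)
  variants <- data.frame(chrom = rep("chrS", n), pos = variants$pos,
                         ref = variants$ref, alt = variants$alt,
                         depth = depth, alt_frac = alt_frac,
                         stringsAsFactors = FALSE)
  variants <- variants[order(variants$pos), , drop = FALSE]
  rownames(variants) <- NULL

  list(variants = variants, composition = comp, masks = masks,
       strain_snps = snp_df, genome = genome,
       truth = list(class_counts = true_counts,
                    n_snp_decoys = nrow(snp_df),
                    n_mask_decoys = n_mask_planted),
       config = config)
}

#' Write a deterministic plain-text fixture bundle
#'
#' Emits a small, fully synthetic data set in the exact formats the readers
#' consume: a replica-culture counts table (TSV) for two strains, a
#' reference genome (FASTA), per-isolate variant calls (VCF 4.2), a
#' low-complexity mask (BED), a strain-background SNP list (VCF) and the
#' generator ground truth (JSON). Re-running with the same seed reproduces
#' the bundle byte for byte.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed controlling the whole bundle.
#' @param genome_length Bases in the shared synthetic genome.
#' @param n_isolates Isolates per genotype (two genotypes are written).
#' @return Invisibly, a named list of the written file paths.
#' @export
write_fixture_bundle <- function(dir, seed = 1L, genome_length = 5e4,
                                 n_isolates = 3L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(seed)
  paths <- list()

  # --- fluctuation counts: a mutator strain and an antimutator strain ---
  cfg_mut <- culture_sim_config(mu = 1e-6, generations = 20, n_cultures = 24)
  cfg_anti <- culture_sim_config(mu = 1e-7, generations = 20, n_cultures = 24)
  e1 <- simulate_cultures(cfg_mut)
  e2 <- simulate_cultures(cfg_anti)
  counts_df <- data.frame(
    strain = rep(c("mutator", "antimutator"), each = 24),
    replicate = rep(seq_len(24), 2),
    mutant_count = c(e1$counts, e2$counts))
  paths$counts <- file.path(dir, "counts.tsv")
  write.table(counts_df, paths$counts, sep = "\t", quote = FALSE,
              row.names = FALSE)

  # --- shared genome / masks / SNPs from the first genotype's generator ---
  base_cfg <- function() spectrum_sim_config(
    genome_length = genome_length,
    class_rates = c("C>T/G>A" = 8e-4, "C>A/G>T" = 4e-4, "C>G/G>C" = 8e-5,
                    "A>G/T>C" = 3e-4, "A>C/T>G" = 8e-5, "A>T/T>A" = 8e-5,
                    insertion = 2e-5, deletion = 4e-5),
    depth_mean = 100, n_snp_decoys = 8, n_mask_decoys = 8)
  anti_rates <- c("C>T/G>A" = 2.5e-4, "C>A/G>T" = 5e-5, "C>G/G>C" = 3e-5,
                  "A>G/T>C" = 2.2e-4, "A>C/T>G" = 3e-5, "A>T/T>A" = 3e-5,
                  insertion = 1e-5, deletion = 2e-5)

  first <- NULL
  truth <- list()
  genotypes <- c("mutator", "antimutator")
  for (gt in genotypes) {
    for (iso in seq_len(n_isolates)) {
      cfg <- base_cfg()
      if (gt == "antimutator") cfg$class_rates <- normalize_class_counts(anti_rates)
      tab <- simulate_variant_table(cfg)
      if (is.null(first)) {
        first <- tab
      } else {
        # one shared reference genome and mask set across isolates
        tab <- resample_on_genome(cfg, first)
      }
      vpath <- file.path(dir, sprintf("variants_%s_%d.vcf", gt, iso))
      write_simple_vcf(tab$variants, vpath,
                       sample_id = sprintf("%s_%d", gt, iso))
      paths[[sprintf("vcf_%s_%d", gt, iso)]] <- vpath
      truth[[sprintf("%s_%d", gt, iso)]] <-
        list(class_counts = as.list(tab$truth$class_counts),
             n_snp_decoys = tab$truth$n_snp_decoys,
             n_mask_decoys = tab$truth$n_mask_decoys)
    }
  }

  paths$fasta <- file.path(dir, "genome.fasta")
  writeLines(c(">chrS synthetic reference",
               chunk_sequence(c("A", "C", "G", "T")[first$genome], 70)),
             paths$fasta)
  paths$bed <- file.path(dir, "masks.bed")
  write.table(first$masks, paths$bed, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  paths$snps <- file.path(dir, "strain_snps.vcf")
  snp_rec <- data.frame(chrom = first$strain_snps$chrom,
                        pos = first$strain_snps$pos,
                        ref = c("A", "C", "G", "T")[first$genome[first$strain_snps$pos]],
                        alt = NA, depth = 100, alt_frac = 0.5)
  snp_rec$alt <- vapply(snp_rec$ref,
                        function(b) setdiff(c("A", "C", "G", "T"), b)[1],
                        character(1))
  write_simple_vcf(snp_rec, paths$snps, sample_id = "background")

  paths$truth <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(seed = seed, genome_length = genome_length,
         fluctuation = list(
           mutator = list(m_true = attr(e1, "truth")$m_true,
                          n_t = attr(e1, "truth")$n_t, epsilon = 1),
           antimutator = list(m_true = attr(e2, "truth")$m_true,
                              n_t = attr(e2, "truth")$n_t, epsilon = 1)),
         spectra = truth),
    paths$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(paths)
}

# Re-draw a variant table on an existing genome/mask set (shared reference
# across isolates of a bundle).
resample_on_genome <- function(config, template) {
  tab <- template
  L <- config$genome_length
  genome <- template$genome
  masked_site <- rep(FALSE, L)
  if (nrow(template$masks)) {
    for (i in seq_len(nrow(template$masks))) {
      masked_site[(template$masks$start[i] + 1L):template$masks$end[i]] <- TRUE
    }
  }
  sim_variants_on(genome, masked_site, template$masks, template$strain_snps,
                  config)
}

# Core variant placement given a genome and mask; used by
# simulate_variant_table siblings sharing one reference.
sim_variants_on <- function(genome, masked_site, masks, strain_snps, config) {
  bases <- c("A", "C", "G", "T")
  L <- length(genome)
  base_counts <- tabulate(genome[!masked_site], nbins = 4L)
  names(base_counts) <- bases
  comp <- genome_composition(unname(base_counts["A"]), unname(base_counts["C"]),
                             unname(base_counts["G"]), unname(base_counts["T"]),
                             total_scored = sum(base_counts),
                             total_sequenced = L)
  cg_sites <- which(!masked_site & (genome == 2L | genome == 3L))
  at_sites <- which(!masked_site & (genome == 1L | genome == 4L))
  all_sites <- which(!masked_site)
  class_alt <- function(class, ref_base) {
    anc <- substr(class, 1, 1); to <- substr(class, 3, 3)
    ifelse(ref_base == anc, to, COMPLEMENT[to])
  }
  rec <- list()
  true_counts <- setNames(numeric(8), mutation_classes())
  used <- logical(L)
  used[strain_snps$pos] <- TRUE
  for (cl in mutation_classes()) {
    sites <- switch(substr(cl, 1, 1), C = cg_sites, A = at_sites, all_sites)
    n_cl <- rpois(1, config$class_rates[cl] * length(sites))
    if (n_cl == 0) next
    pos <- sample(sites, n_cl)
    pos <- pos[!used[pos]]
    used[pos] <- TRUE
    n_cl <- length(pos)
    true_counts[cl] <- n_cl
    if (n_cl == 0) next
    rb <- bases[genome[pos]]
    if (cl == "insertion") {
      ref <- rb; alt <- paste0(rb, bases[sample.int(4L, n_cl, TRUE)])
    } else if (cl == "deletion") {
      pos <- pmin(pos, L - 1L)
      ref <- paste0(bases[genome[pos]], bases[genome[pos + 1L]])
      alt <- bases[genome[pos]]
    } else {
      ref <- rb; alt <- unname(class_alt(cl, rb))
    }
    rec[[cl]] <- data.frame(pos = pos, ref = ref, alt = alt,
                            stringsAsFactors = FALSE)
  }
  if (nrow(strain_snps)) {
    rb <- bases[genome[strain_snps$pos]]
    alt <- vapply(rb, function(b) sample(setdiff(bases, b), 1), character(1))
    rec[["snp_decoy"]] <- data.frame(pos = strain_snps$pos, ref = rb,
                                     alt = unname(alt))
  }
  if (config$n_mask_decoys > 0 && any(masked_site)) {
    mpos <- sample(which(masked_site), config$n_mask_decoys)
    rb <- bases[genome[mpos]]
    alt <- vapply(rb, function(b) sample(setdiff(bases, b), 1), character(1))
    rec[["mask_decoy"]] <- data.frame(pos = mpos, ref = rb, alt = unname(alt))
  }
  variants <- do.call(rbind, rec)
  n <- nrow(variants)
  depth <- pmax(1L, rpois(n, config$depth_mean))
  alt_frac <- if (config$vaf_noise) rbinom(n, depth, 0.5) / depth else
    rep(0.5, n)
  variants <- data.frame(chrom = rep("chrS", n), pos = variants$pos,
                         ref = variants$ref, alt = variants$alt,
                         depth = depth, alt_frac = alt_frac,
                         stringsAsFactors = FALSE)
  variants <- variants[order(variants$pos), , drop = FALSE]
  rownames(variants) <- NULL
  list(variants = variants, composition = comp, masks = masks,
       strain_snps = strain_snps, genome = genome,
       truth = list(class_counts = true_counts,
                    n_snp_decoys = nrow(strain_snps),
                    n_mask_decoys = config$n_mask_decoys),
       config = config)
}

chunk_sequence <- function(chars, width) {
  n <- length(chars)
  starts <- seq(1L, n, by = width)
  vapply(starts, function(s) paste(chars[s:min(s + width - 1L, n)],
                                   collapse = ""), character(1))
}
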