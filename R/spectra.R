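#' Strand-collapsed mutation classes
#'
#' The six base-substitution classes (pyrimidine-anchored pair notation, so
#' a G-to-A change is reported together with its complement as "C>T/G>A")
#' plus insertions and deletions.
#'
#' @return Character vector of the eight class labels in canonical order.
#' @export
mutation_classes <- function() {
  c("C>T/G>A", "C>A/G>T", "C>G/G>C",
    "A>G/T>C", "A>C/T>G", "A>T/T>A",
    "insertion", "deletion")
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Classify a mutation into a strand-collapsed class
#'
#' Single-base substitutions map to the pyrimidine-anchored pair label
#' (e.g. both G>A and C>T give "C>T/G>A"). Alleles of different length with
#' a shared leading base are classified as insertion (alt longer) or
#' deletion (alt shorter). Equal-length multi-base substitutions are not
#' supported and return `"unsupported"` with a warning; callers exclude
#' them.
#'
#' @param ref,alt Reference and alternate allele strings (A/C/G/T only,
#'   non-empty, `ref != alt`). Vectorized; vectors are recycled to a common
#'   length.
#' @return Character vector of class labels (see [mutation_classes()]).
#' @examples
#' classify_mutation("G", "A")   # "C>T/G>A"
#' classify_mutation("A", "AT")  # "insertion"
#' @export
classify_mutation <- function(ref, alt) {
  n <- max(length(ref), length(alt))
  ref <- toupper(rep_len(as.character(ref), n))
  alt <- toupper(rep_len(as.character(alt), n))
  if (any(!nzchar(ref)) || any(!nzchar(alt))) {
    stop("alleles must be non-empty DNA strings", call. = FALSE)
  }
  if (any(grepl("[^ACGT]", ref)) || any(grepl("[^ACGT]", alt))) {
    stop("alleles must contain only A, C, G, T", call. = FALSE)
  }
  if (any(ref == alt)) {
    stop("'ref' and 'alt' must differ", call. = FALSE)
  }

  lr <- nchar(ref)
  la <- nchar(alt)
  out <- character(n)

  sub1 <- lr == 1L & la == 1L
  if (any(sub1)) {
    r <- ref[sub1]
    a <- alt[sub1]
    flip <- r %in% c("G", "T")
    r[flip] <- COMPLEMENT[r[flip]]
    a[flip] <- COMPLEMENT[a[flip]]
    out[sub1] <- paste0(r, ">", a, "/", COMPLEMENT[r], ">", COMPLEMENT[a])
  }
  ins <- la > lr
  del <- la < lr
  out[ins] <- "insertion"
  out[del] <- "deletion"
  bad <- !sub1 & !ins & !del
  if (any(bad)) {
    warning(sum(bad), " equal-length multi-base substitution(s) are not ",
            "supported; classified as 'unsupported' and excluded downstream",
            call. = FALSE)
    out[bad] <- "unsupported"
  }
  out
}

#' Flag called variants by the scoring rules
#'
#' Applies, in precedence order, the filters used to score
#' mutation-accumulation variants: strain-background SNP, low coverage
#' (depth must exceed `min_depth`, so with the default 20 a depth of 21
#' passes), masked (low-complexity) region, and heterozygous allele
#' fraction outside `[vaf_low, vaf_high]` (bounds inclusive). Exactly one
#' terminal flag is assigned per record; the operation is deterministic and
#' idempotent.
#'
#' @param records Data frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, `depth`, `alt_frac`.
#' @param min_depth Depth threshold; records with `depth <= min_depth` are
#'   flagged `low_coverage`.
#' @param vaf_low,vaf_high Inclusive bounds on the alternate-allele
#'   fraction for a heterozygous diploid call.
#' @param masks Data frame of masked intervals with columns `chrom`,
#'   `start`, `end` (0-based half-open, BED convention), or NULL.
#' @param strain_snps Data frame of strain-background SNP sites with
#'   columns `chrom`, `pos` (1-based), or NULL.
#' @return `records` with a `flag` column (one of `strain_snp`,
#'   `low_coverage`, `masked`, `vaf_out_of_range`, `pass`).
#' @export
filter_variants <- function(records, min_depth = 20L, vaf_low = 0.40,
                            vaf_high = 0.60, masks = NULL,
                            strain_snps = NULL) {
  need <- c("chrom", "pos", "ref", "alt", "depth", "alt_frac")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("'records' is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(records) == 0) {
    records$flag <- character(0)
    return(records)
  }
  if (any(records$pos < 1)) stop("positions must be >= 1", call. = FALSE)
  if (any(records$alt_frac < 0 | records$alt_frac > 1)) {
    stop("'alt_frac' must be in [0, 1]", call. = FALSE)
  }
  if (!is.null(masks) && nrow(masks) > 0 && any(masks$end <= masks$start)) {
    stop("malformed mask interval: end <= start", call. = FALSE)
  }

  is_snp <- if (is.null(strain_snps) || nrow(strain_snps) == 0) {
    rep(FALSE, nrow(records))
  } else {
    paste(records$chrom, records$pos) %in%
      paste(strain_snps$chrom, strain_snps$pos)
  }
  is_masked <- in_masked_region(records$chrom, records$pos, masks)

  flag <- rep("pass", nrow(records))
  flag[records$alt_frac < vaf_low | records$alt_frac > vaf_high] <-
    "vaf_out_of_range"
  flag[is_masked] <- "masked"
  flag[records$depth <= min_depth] <- "low_coverage"
  flag[is_snp] <- "strain_snp"
  records$flag <- flag
  records
}

# TRUE where (chrom, pos 1-based) falls in a 0-based half-open interval set.
in_masked_region <- function(chrom, pos, masks) {
  if (is.null(masks) || nrow(masks) == 0) return(rep(FALSE, length(chrom)))
  out <- rep(FALSE, length(chrom))
  for (ch in unique(masks$chrom)) {
    mk <- masks[masks$chrom == ch, , drop = FALSE]
    sel <- which(chrom == ch)
    if (!length(sel)) next
    p0 <- pos[sel] - 1L  # to 0-based
    hit <- vapply(p0, function(p) any(p >= mk$start & p < mk$end), logical(1))
    out[sel] <- hit
  }
  out
}

#' Genome composition: the normalization denominators
#'
#' Counts of scorable reference bases by identity, the total number of
#' scored bases and the total number of bases sequenced. Substitution
#' frequencies are normalized by the count of bases that could produce the
#' class; indel frequencies by a genome-wide denominator.
#'
#' @param n_A,n_C,n_G,n_T Counts of scorable A/C/G/T reference bases.
#' @param total_scored Total scorable bases (>= sum of the four counts;
#'   ambiguous bases are excluded from the four counts).
#' @param total_sequenced Total bases sequenced (>= `total_scored`).
#' @return Object of class `genome_composition`.
#' @export
genome_composition <- function(n_A, n_C, n_G, n_T,
                               total_scored = n_A + n_C + n_G + n_T,
                               total_sequenced = total_scored) {
  counts <- c(n_A, n_C, n_G, n_T)
  if (any(counts < 0) || total_scored < 0 || total_sequenced < 0) {
    stop("composition counts must be >= 0", call. = FALSE)
  }
  if (sum(counts) > total_scored || total_scored > total_sequenced) {
    stop("need n_A+n_C+n_G+n_T <= total_scored <= total_sequenced",
         call. = FALSE)
  }
  structure(list(n_A = n_A, n_C = n_C, n_G = n_G, n_T = n_T,
                 total_scored = total_scored,
                 total_sequenced = total_sequenced),
            class = "genome_composition")
}

#' Per-class mutation frequencies (mutations per scorable base)
#'
#' Divides each class count by the number of scored genome positions that
#' could produce that class: classes anchored at C:G pairs use
#' `n_C + n_G`, classes at A:T pairs use `n_A + n_T`. Indel counts are
#' divided by `total_scored` (default) or `total_sequenced`.
#'
#' @param counts Named numeric vector of per-class counts (names from
#'   [mutation_classes()]; missing classes count 0).
#' @param comp A [genome_composition()].
#' @param indel_denominator `"scored"` or `"sequenced"`.
#' @return Named numeric vector of frequencies over all eight classes.
#' @export
class_frequencies <- function(counts, comp,
                              indel_denominator = c("scored", "sequenced")) {
  stopifnot(inherits(comp, "genome_composition"))
  indel_denominator <- match.arg(indel_denominator)
  counts <- normalize_class_counts(counts)
  den_cg <- comp$n_C + comp$n_G
  den_at <- comp$n_A + comp$n_T
  den_indel <- if (indel_denominator == "scored") comp$total_scored else
    comp$total_sequenced
  den <- c("C>T/G>A" = den_cg, "C>A/G>T" = den_cg, "C>G/G>C" = den_cg,
           "A>G/T>C" = den_at, "A>C/T>G" = den_at, "A>T/T>A" = den_at,
           insertion = den_indel, deletion = den_indel)
  bad <- den == 0 & counts > 0
  if (any(bad)) {
    stop("zero denominator with nonzero count for class(es): ",
         paste(names(counts)[bad], collapse = ", "), call. = FALSE)
  }
  out <- ifelse(den > 0, counts / den, 0)
  names(out) <- mutation_classes()
  out
}

#' Per-class mutation fractions (share of total mutations)
#'
#' Each class count divided by the total number of observed mutations. With
#' a zero total, all fractions are zero and the result carries attribute
#' `empty = TRUE`.
#'
#' @inheritParams class_frequencies
#' @return Named numeric vector of fractions summing to 1 (or all zero).
#' @export
class_fractions <- function(counts) {
  counts <- normalize_class_counts(counts)
  total <- sum(counts)
  if (total == 0) {
    out <- counts * 0
    attr(out, "empty") <- TRUE
    return(out)
  }
  counts / total
}

normalize_class_counts <- function(counts) {
  cls <- mutation_classes()
  if (is.null(names(counts))) {
    if (length(counts) != length(cls)) {
      stop("unnamed 'counts' must have length ", length(cls), call. = FALSE)
    }
    names(counts) <- cls
  }
  unknown <- setdiff(names(counts), c(cls, "unsupported"))
  if (length(unknown)) {
    stop("unknown mutation class(es): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (any(counts < 0)) stop("class counts must be >= 0", call. = FALSE)
  out <- setNames(numeric(length(cls)), cls)
  keep <- intersect(names(counts), cls)
  out[keep] <- counts[keep]
  out
}

#' Generations of growth implied by a colony size
#'
#' A colony grown from a single cell through g doublings has 2^g cells, so
#' the number of generations is `ceiling(log2(n_cells))`.
#'
#' @param n_cells Number of cells in the colony (>= 1).
#' @return Integer number of generations.
#' @examples
#' generations_from_cells(1e6)  # 20
#' generations_from_cells(1e5)  # 17
#' @export
generations_from_cells <- function(n_cells) {
  if (!is.numeric(n_cells) || any(is.na(n_cells)) || any(n_cells < 1)) {
    stop("'n_cells' must be >= 1", call. = FALSE)
  }
  as.integer(ceiling(log2(n_cells)))
}

#' Genome-wide mutation rate per cell division
#'
#' Total accumulated mutations divided by the number of generations over
#' which they arose.
#'
#' @param total_mutations Total mutations observed in one genome (>= 0).
#' @param generations Generations of growth (>= 1).
#' @return Mutations per cell division.
#' @examples
#' genome_wide_rate(1780, 20)  # 89
#' @export
genome_wide_rate <- function(total_mutations, generations) {
  if (!is.numeric(generations) || any(generations < 1)) {
    stop("'generations' must be >= 1", call. = FALSE)
  }
  if (!is.numeric(total_mutations) || any(total_mutations < 0)) {
    stop("'total_mutations' must be >= 0", call. = FALSE)
  }
  total_mutations / generations
}

#' Spectrum summary for one isolate
#'
#' Collects per-class counts, frequencies and fractions for one sequenced
#' isolate, from a filtered variant table (only records with flag `pass`
#' are scored; `unsupported` classes are excluded).
#'
#' @param variants A variant table as returned by [filter_variants()]; or
#'   NULL if `counts` is given directly.
#' @param comp A [genome_composition()].
#' @param counts Optional named per-class counts, bypassing `variants`.
#' @param indel_denominator Passed to [class_frequencies()].
#' @return Object of class `spectrum_summary` with `counts`, `frequencies`,
#'   `fractions`, `total_mutations`, `n_isolates = 1`.
#' @export
spectrum_summary <- function(variants = NULL, comp, counts = NULL,
                             indel_denominator = "scored") {
  if (is.null(counts)) {
    stopifnot(is.data.frame(variants))
    if (!"flag" %in% names(variants)) {
      stop("'variants' must be filtered first (missing 'flag' column)",
           call. = FALSE)
    }
    keep <- variants[variants$flag == "pass", , drop = FALSE]
    cls <- if (nrow(keep)) classify_mutation(keep$ref, keep$alt) else
      character(0)
    cls <- cls[cls != "unsupported"]
    tab <- table(factor(cls, levels = mutation_classes()))
    counts <- setNames(as.numeric(tab), names(tab))
  }
  counts <- normalize_class_counts(counts)
  structure(list(counts = counts,
                 frequencies = class_frequencies(counts, comp,
                                                 indel_denominator),
                 fractions = class_fractions(counts),
                 total_mutations = sum(counts),
                 n_isolates = 1L),
            class = "spectrum_summary")
}

#' Pool per-isolate spectra for a genotype group
#'
#' Computes the per-class mean and sample standard deviation of the
#' frequencies and fractions across independent isolates of one genotype
#' (the error bars of a spectrum figure), and sums the counts. With a
#' single isolate the standard deviations are reported as 0 and the result
#' carries `single_isolate = TRUE`.
#'
#' @param summaries List of [spectrum_summary()] objects (>= 1).
#' @return Object of class `spectrum_summary` with added fields
#'   `freq_mean`, `freq_sd`, `frac_mean`, `frac_sd`, `n_isolates`, and a
#'   `per_isolate` list.
#' @export
summarize_group <- function(summaries) {
  if (length(summaries) < 1) stop("need at least 1 isolate", call. = FALSE)
  stopifnot(all(vapply(summaries, inherits, logical(1), "spectrum_summary")))
  cls <- mutation_classes()
  fr <- t(vapply(summaries, function(s) s$frequencies[cls], numeric(length(cls))))
  fc <- t(vapply(summaries, function(s) s$fractions[cls], numeric(length(cls))))
  cn <- t(vapply(summaries, function(s) s$counts[cls], numeric(length(cls))))
  one <- length(summaries) == 1L
  sdev <- function(mat) {
    if (one) setNames(numeric(length(cls)), cls) else apply(mat, 2, sd)
  }
  out <- list(counts = colSums(cn),
              freq_mean = colMeans(fr), freq_sd = sdev(fr),
              frac_mean = colMeans(fc), frac_sd = sdev(fc),
              total_mutations = sum(cn),
              n_isolates = length(summaries),
              single_isolate = one,
              per_isolate = summaries)
  class(out) <- c("spectrum_group", "spectrum_summary")
  out
}

#' @export
print.spectrum_summary <- function(x, ...) {
  cat("Mutation spectrum (", x$n_isolates, " isolate(s), ",
      x$total_mutations, " mutations)\n", sep = "")
  if (inherits(x, "spectrum_group")) {
    df <- data.frame(class = mutation_classes(),
                     count = as.numeric(x$counts),
                     freq_mean = signif(x$freq_mean, 3),
                     freq_sd = signif(x$freq_sd, 3),
                     frac_mean = signif(x$frac_mean, 3),
                     frac_sd = signif(x$frac_sd, 3))
  } else {
    df <- data.frame(class = mutation_classes(),
                     count = as.numeric(x$counts),
                     frequency = signif(x$frequencies, 3),
                     fraction = signif(x$fractions, 3))
  }
  print(df, row.names = FALSE)
  invisible(x)
}
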