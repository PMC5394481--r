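#' Read a replica-culture counts table
#'
#' Reads a TSV/CSV file with header columns `strain`, `replicate`,
#' `mutant_count` (one row per culture) and groups it into one
#' [fluctuation_experiment()] per strain. Plating efficiency and mean CFU
#' are supplied per strain (named vectors) or as scalars recycled to all
#' strains.
#'
#' @param path File path; `.csv` is read comma-separated, anything else
#'   tab-separated.
#' @param epsilon Plating efficiency per strain (scalar or named vector).
#' @param n_t Mean colony-forming units per strain (scalar or named
#'   vector).
#' @return Named list of `fluctuation_experiment` objects (empty list, with
#'   a warning, for an empty file).
#' @export
read_counts_table <- function(path, epsilon = 1, n_t) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("strain", "replicate", "mutant_count")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("counts table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0) {
    warning("counts table ", path, " is empty", call. = FALSE)
    return(list())
  }
  cnt <- suppressWarnings(as.numeric(df$mutant_count))
  bad <- which(is.na(cnt) | cnt < 0 | cnt != floor(cnt))
  if (length(bad)) {
    stop("non-integer mutant_count in ", path, " at data line ", bad[1],
         " (value '", df$mutant_count[bad[1]], "')", call. = FALSE)
  }
  pick <- function(x, strain, what) {
    if (length(x) == 1L && is.null(names(x))) return(unname(x))
    if (is.null(names(x)) || !strain %in% names(x)) {
      stop("no ", what, " supplied for strain '", strain, "'", call. = FALSE)
    }
    unname(x[[strain]])
  }
  out <- list()
  for (s in unique(df$strain)) {
    rows <- df[df$strain == s, , drop = FALSE]
    if (anyDuplicated(rows$replicate)) {
      stop("duplicate replicate IDs for strain '", s, "' in ", path,
           call. = FALSE)
    }
    out[[s]] <- fluctuation_experiment(
      strain = s, counts = cnt[df$strain == s],
      epsilon = pick(epsilon, s, "epsilon"),
      n_t = pick(n_t, s, "n_t"))
  }
  out
}

#' Write a minimal VCF 4.2 file for a variant table
#'
#' Emits the synthetic variant records with `DP` (depth) and `AF`
#' (alternate-allele fraction) INFO fields; parseable by standard VCF
#' readers.
#'
#' @param variants Data frame with chrom, pos, ref, alt, depth, alt_frac.
#' @param path Output path.
#' @param sample_id Label written into the header.
#' @return Invisibly, `path`.
#' @export
write_simple_vcf <- function(variants, path, sample_id = "sample") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##source=mutassay synthetic generator (%s)", sample_id),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    paste0("##INFO=<ID=AF,Number=1,Type=Float,Description=",
           "\"Alternate allele read fraction\">"),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(variants)) {
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\t.\tDP=%d;AF=%.6f",
                       variants$chrom, as.integer(variants$pos),
                       variants$ref, variants$alt,
                       as.integer(variants$depth), variants$alt_frac), con)
  }
  invisible(path)
}

#' Read the variant-calling inputs for the spectrum pipeline
#'
#' Parses a variant VCF (multi-allelic lines decomposed into biallelic
#' records), an optional strain-background SNP VCF, an optional BED mask
#' and an optional reference FASTA. The genome composition is computed from
#' the FASTA excluding masked intervals and ambiguity codes.
#'
#' @param vcf_path Variant calls (VCF 4.x with `DP` and `AF` INFO fields).
#' @param snp_path Optional strain-background SNP list (VCF).
#' @param bed_path Optional low-complexity mask (BED, 0-based half-open).
#' @param fasta_path Optional reference genome (FASTA).
#' @return List with `variants`, `strain_snps`, `masks`, `composition`
#'   (NULL when the corresponding input is not given).
#' @export
read_variants <- function(vcf_path, snp_path = NULL, bed_path = NULL,
                          fasta_path = NULL) {
  variants <- read_vcf_records(vcf_path)
  strain_snps <- if (!is.null(snp_path)) {
    read_vcf_records(snp_path)[, c("chrom", "pos")]
  }
  masks <- if (!is.null(bed_path)) {
    gr <- as.data.frame(rtracklayer::import(bed_path, format = "BED"))
    data.frame(chrom = as.character(gr$seqnames),
               start = gr$start - 1L,  # GRanges is 1-based; back to 0-based
               end = gr$end,
               stringsAsFactors = FALSE)
  }
  composition <- NULL
  if (!is.null(fasta_path)) {
    genome <- Biostrings::readDNAStringSet(fasta_path)
    names(genome) <- sub("\\s.*$", "", names(genome))
    bad <- setdiff(unique(variants$chrom), names(genome))
    if (length(bad)) {
      stop("chromosome(s) in VCF absent from FASTA: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    composition <- composition_from_fasta(genome, masks)
  }
  list(variants = variants, strain_snps = strain_snps, masks = masks,
       composition = composition)
}

read_vcf_records <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      depth = numeric(0), alt_frac = numeric(0)))
  }
  dp <- suppressWarnings(as.numeric(vcfR::extract.info(v, "DP")))
  af <- suppressWarnings(as.numeric(vcfR::extract.info(v, "AF")))
  rec <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                    ref = fix$REF, alt = fix$ALT,
                    depth = dp, alt_frac = af, stringsAsFactors = FALSE)
  # decompose multi-allelic lines into biallelic records
  multi <- grepl(",", rec$alt)
  if (any(multi)) {
    expanded <- lapply(which(multi), function(i) {
      alts <- strsplit(rec$alt[i], ",", fixed = TRUE)[[1]]
      out <- rec[rep(i, length(alts)), , drop = FALSE]
      out$alt <- alts
      out
    })
    rec <- rbind(rec[!multi, , drop = FALSE], do.call(rbind, expanded))
    rec <- rec[order(rec$chrom, rec$pos), , drop = FALSE]
  }
  rownames(rec) <- NULL
  rec
}

#' Genome composition from a reference sequence
#'
#' Counts scorable A/C/G/T bases over the unmasked part of the genome.
#' Ambiguity codes are excluded from the four base counts but masked bases
#' are excluded from `total_scored` entirely; `total_sequenced` is the full
#' genome length.
#'
#' @param genome A `Biostrings::DNAStringSet` (or object coercible to one).
#' @param masks Optional data frame of 0-based half-open intervals
#'   (`chrom`, `start`, `end`).
#' @return A [genome_composition()].
#' @export
composition_from_fasta <- function(genome, masks = NULL) {
  if (!methods::is(genome, "DNAStringSet")) {
    genome <- Biostrings::DNAStringSet(genome)
  }
  total_sequenced <- sum(Biostrings::width(genome))
  counts <- c(A = 0, C = 0, G = 0, T = 0)
  total_scored <- 0
  for (i in seq_along(genome)) {
    chrom <- names(genome)[i]
    seq_i <- genome[[i]]
    keep <- rep(TRUE, length(seq_i))
    if (!is.null(masks) && nrow(masks)) {
      mk <- masks[masks$chrom == chrom, , drop = FALSE]
      for (j in seq_len(nrow(mk))) {
        lo <- max(1L, mk$start[j] + 1L)
        hi <- min(length(seq_i), mk$end[j])
        if (hi >= lo) keep[lo:hi] <- FALSE
      }
    }
    if (!any(keep)) next
    sub <- seq_i[which(keep)]
    lf <- Biostrings::letterFrequency(sub, letters = c("A", "C", "G", "T"))
    counts <- counts + as.numeric(lf)
    total_scored <- total_scored + length(sub)
  }
  genome_composition(unname(counts[1]), unname(counts[2]),
                     unname(counts[3]), unname(counts[4]),
                     total_scored = total_scored,
                     total_sequenced = total_sequenced)
}

#' Format a per-division rate the way rate tables print it
#'
#' Rates are displayed in units of 1e-7 per cell division to 2 significant
#' figures with the 95% CI in parentheses, e.g. `"2.2 (1.3, 3.4)"`.
#'
#' @param rate,ci_low,ci_high Per-division rate and CI (unscaled).
#' @param scale Display scale (default 1e-7).
#' @return Character vector.
#' @export
format_rate_display <- function(rate, ci_low, ci_high, scale = 1e-7) {
  fmt <- function(x) as.character(signif(x / scale, 2))
  sprintf("%s (%s, %s)", fmt(rate), fmt(ci_low), fmt(ci_high))
}

#' Write rate and comparison reports (TSV + JSON)
#'
#' Renders a list of [estimate_rate()] results (and optionally
#' [lrt_compare()] results) as a machine-readable TSV and a JSON document.
#' The display column follows the conventional table layout (rate x 1e-7
#' with 95% CI in parentheses); adjusted p-values above 0.05 are shown as
#' `"ns"`. The JSON stores unscaled values plus a provenance block echoing
#' every parameter.
#'
#' @param rates List of `rate_estimate` objects.
#' @param comparisons Optional list of `rate_comparison` objects.
#' @param path_prefix Output path prefix; writes `<prefix>_rates.tsv`,
#'   `<prefix>.json` and, when comparisons are given,
#'   `<prefix>_comparisons.tsv`.
#' @param provenance Optional named list echoed into the JSON report.
#' @return Invisibly, the list of written paths.
#' @export
write_report <- function(rates, comparisons = NULL, path_prefix,
                         provenance = list()) {
  rates_df <- do.call(rbind, lapply(rates, function(r) {
    data.frame(strain = if (is.null(r$strain)) NA_character_ else r$strain,
               n_cultures = if (is.null(r$n_cultures)) NA else r$n_cultures,
               m_hat = r$m_hat, rate = r$rate,
               ci_low = r$ci_low, ci_high = r$ci_high,
               display = format_rate_display(r$rate, r$ci_low, r$ci_high),
               stringsAsFactors = FALSE)
  }))
  if (is.null(rates_df)) {
    rates_df <- data.frame(strain = character(0), n_cultures = integer(0),
                           m_hat = numeric(0), rate = numeric(0),
                           ci_low = numeric(0), ci_high = numeric(0),
                           display = character(0))
  }
  paths <- list(rates_tsv = paste0(path_prefix, "_rates.tsv"),
                json = paste0(path_prefix, ".json"))
  write.table(rates_df, paths$rates_tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)

  comp_df <- NULL
  if (!is.null(comparisons)) {
    comp_df <- do.call(rbind, lapply(comparisons, function(x) {
      data.frame(pair = paste0(x$strain_a, " vs ", x$strain_b),
                 lrt_stat = x$lrt_stat, p_raw = x$p_raw, p_adj = x$p_adj,
                 significance = if (!is.na(x$p_adj) && x$p_adj > 0.05) "ns"
                                else format(signif(x$p_adj, 2)),
                 fold = x$fold, stringsAsFactors = FALSE)
    }))
    if (is.null(comp_df)) {
      comp_df <- data.frame(pair = character(0), lrt_stat = numeric(0),
                            p_raw = numeric(0), p_adj = numeric(0),
                            significance = character(0), fold = numeric(0))
    }
    paths$comparisons_tsv <- paste0(path_prefix, "_comparisons.tsv")
    write.table(comp_df, paths$comparisons_tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }

  jsonlite::write_json(
    list(rates = rates_df, comparisons = comp_df, provenance = provenance),
    paths$json, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(paths)
}

#' Published canavanine-resistance mutation rates for the study strains
#'
#' The published per-division Can-r mutation rates (x 1e-7) with 95%
#' confidence intervals, Bonferroni-adjusted significance calls and
#' antimutator fold effects, for wild-type and mutant Pol delta alleles in
#' MMR-proficient and Msh2-deficient diploids. Used as worked-example
#' inputs for the fold-effect and mutator-ratio checks.
#'
#' @return Data frame with columns `background` (POL3, pol3-01,
#'   pol3-L612M, pol3-01,L612M), `mmr` (MSH2 or msh2), `allele` (control or
#'   the eex substitution), `rate`, `ci_low`, `ci_high` (x 1e-7 per cell
#'   division), `p_display` (printed adjusted p-value or "ns"), `effect`
#'   (printed fold effect; NA for controls and inviable strains).
#' @export
published_rate_table <- function() {
  path <- system.file("extdata", "published_canr_rates.tsv",
                      package = "mutassay")
  read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
}
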