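# Somatic-mutation association: MAF ingestion, mutational burden,
# hypermutation/MMR exclusion, gene-size filter, per-gene Fisher screening,
# substitution spectra, pairwise co-occurrence / mutual exclusivity.

maf_required_columns <- function() {
  c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification",
    "Variant_Type", "Chromosome", "Start_Position", "Reference_Allele",
    "Tumor_Seq_Allele2")
}

#' Read a MAF-like somatic mutation table
#'
#' Parses a tab-separated MAF with the standard column names, drops exact
#' duplicate records and validates SNP records (single-base ref and alt,
#' ref != alt). Silent variants are retained in the table; downstream
#' "mutated gene" logic excludes them by default via its `classes` argument.
#'
#' @param path path to the MAF TSV.
#' @return data.frame of mutation records (class `mg_maf`).
#' @export
read_maf <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  # read as character: allele columns like "T" must not become logicals
  maf <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE, comment.char = "#",
                           colClasses = "character")
  miss <- setdiff(maf_required_columns(), names(maf))
  if (length(miss))
    stopf("MAF lacks required column(s): %s", paste(miss, collapse = ", "))
  maf <- maf[maf_required_columns()]
  maf$Start_Position <- as.numeric(maf$Start_Position)
  maf <- maf[!duplicated(maf), , drop = FALSE]
  snp <- maf$Variant_Type == "SNP"
  bad <- snp & (nchar(maf$Reference_Allele) != 1 |
                  nchar(maf$Tumor_Seq_Allele2) != 1 |
                  maf$Reference_Allele == maf$Tumor_Seq_Allele2)
  if (any(bad))
    stopf("%d SNP record(s) violate single-base ref != alt (first at row %d)",
          sum(bad), which(bad)[1])
  rownames(maf) <- NULL
  class(maf) <- c("mg_maf", "data.frame")
  maf
}

# records restricted to a variant-classification set; NULL keeps everything
filter_classes <- function(records, classes) {
  if (is.null(classes)) return(records)
  records[records$Variant_Classification %in% classes, , drop = FALSE]
}

#' Tumor mutational burden per sample
#'
#' Mutation records per sample divided by the captured exome size in Mb.
#' Samples in `samples` without records get 0.
#'
#' @param records a MAF data.frame (see [read_maf()]).
#' @param samples sample ids to report; defaults to those in `records`.
#' @param exome_mb exome size denominator in Mb (default 38).
#' @param classes variant classifications counted; `NULL` (default) counts
#'   every record.
#' @return named numeric vector, mutations per Mb.
#' @export
compute_tmb <- function(records, samples = NULL, exome_mb = 38,
                        classes = NULL) {
  assert_scalar_number(exome_mb, "exome_mb", 1e-9)
  records <- filter_classes(records, classes)
  samples <- samples %||% sort(unique(records$Tumor_Sample_Barcode))
  counts <- table(factor(records$Tumor_Sample_Barcode, levels = samples))
  stats::setNames(as.numeric(counts) / exome_mb, samples)
}

#' Exclude hypermutated samples explained by MMR / polymerase mutations
#'
#' A sample is excluded iff its tumor mutational burden exceeds
#' `tmb_threshold` AND it carries a non-silent mutation in one of the
#' mismatch-repair or replicative-polymerase genes; hypermutated samples
#' without such a mutation are retained.
#'
#' @param records a MAF data.frame.
#' @param samples sample ids under consideration.
#' @param tmb_threshold hypermutation bound in mutations/Mb (default 10,
#'   strictly greater).
#' @param exome_mb exome size in Mb.
#' @param exclusion_genes genes whose mutation explains hypermutation
#'   (default MSH2, MSH6, MLH1, PMS2, POLD1, POLE).
#' @param classes variant classes counted toward the burden (`NULL` = all).
#' @return list with `retained` (sample ids), `excluded` (data.frame:
#'   sample, tmb, trigger genes), `tmb` (the full named vector), and
#'   `n_hypermutated`.
#' @export
hypermutation_filter <- function(records, samples = NULL, tmb_threshold = 10,
                                 exome_mb = 38,
                                 exclusion_genes = mmr_polymerase_genes(),
                                 classes = NULL) {
  samples <- samples %||% sort(unique(records$Tumor_Sample_Barcode))
  tmb <- compute_tmb(records, samples, exome_mb = exome_mb,
                     classes = classes)
  nonsil <- filter_classes(records, nonsilent_classes())
  carriers <- split(nonsil$Hugo_Symbol, nonsil$Tumor_Sample_Barcode)
  triggers <- lapply(samples, function(s)
    sort(intersect(unique(carriers[[s]]), exclusion_genes)))
  names(triggers) <- samples
  hyper <- tmb > tmb_threshold
  excl <- hyper & vapply(triggers, length, integer(1)) > 0
  list(
    retained = samples[!excl],
    excluded = data.frame(
      sample = samples[excl],
      tmb = unname(tmb[excl]),
      trigger = vapply(triggers[excl], paste, character(1), collapse = ","),
      stringsAsFactors = FALSE),
    tmb = tmb,
    n_hypermutated = sum(hyper)
  )
}

#' Drop mutations in very large genes
#'
#' Keeps records in genes with fewer than `max_aa` amino acids (strict);
#' genes absent from the length table are retained and reported in the
#' `unmapped_genes` attribute.
#'
#' @param records a MAF data.frame.
#' @param protein_lengths data.frame with columns `gene`, `aa_length`, or a
#'   named numeric vector. [default_gene_lengths()] ships a minimal
#'   annotation of common colorectal-cancer genes.
#' @param max_aa size bound in amino acids (default 5000).
#' @return the filtered records, with attribute `unmapped_genes`.
#' @export
gene_size_filter <- function(records, protein_lengths, max_aa = 5000) {
  if (is.data.frame(protein_lengths)) {
    if (!all(c("gene", "aa_length") %in% names(protein_lengths)))
      stopf("'protein_lengths' needs columns gene, aa_length")
    len <- stats::setNames(protein_lengths$aa_length, protein_lengths$gene)
  } else len <- protein_lengths
  glen <- len[records$Hugo_Symbol]
  unmapped <- sort(unique(records$Hugo_Symbol[is.na(glen)]))
  keep <- is.na(glen) | glen < max_aa
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unmapped_genes") <- unmapped
  out
}

#' Minimal gene-length annotation
#'
#' Protein lengths (amino acids) for a small set of genes commonly mutated
#' in colorectal cancer, read from the annotation shipped with the package.
#'
#' @return data.frame with columns `gene`, `aa_length`.
#' @export
default_gene_lengths <- function() {
  utils::read.delim(system.file("extdata", "gene_aa_lengths.tsv",
                                package = "mgscreen"),
                    stringsAsFactors = FALSE)
}

#' Per-gene mutation frequency
#'
#' Fraction of samples carrying at least one qualifying record per gene.
#'
#' @param records a MAF data.frame.
#' @param samples sample ids forming the denominator.
#' @param classes qualifying variant classes (default non-silent).
#' @return named numeric vector, sorted decreasing.
#' @export
mutation_frequency <- function(records, samples,
                               classes = nonsilent_classes()) {
  if (!length(samples)) stopf("empty sample set")
  rec <- filter_classes(records, classes)
  rec <- rec[rec$Tumor_Sample_Barcode %in% samples, , drop = FALSE]
  pairs <- unique(rec[c("Hugo_Symbol", "Tumor_Sample_Barcode")])
  freq <- table(pairs$Hugo_Symbol) / length(samples)
  sort(stats::setNames(as.numeric(freq), names(freq)), decreasing = TRUE)
}

#' Per-gene Fisher screen between Mg groups
#'
#' For every gene mutated in at least `min_mutated` samples, builds the 2x2
#' mutated/wild-type x High-Mg/Low-Mg table and computes the two-sided
#' Fisher exact p-value (probability-mass convention: sum of all tables
#' with point probability at or below the observed one) and the odds ratio
#' `(a*d)/(b*c)`; when any cell is zero a 0.5-continuity-corrected odds
#' ratio is reported separately. Raw p at `alpha` is the screening
#' criterion; BH q-values are reported alongside.
#'
#' @param records a MAF data.frame.
#' @param groups an `mg_groups` from [dichotomize_mg()], or a named
#'   character vector of `"High-Mg"`/`"Low-Mg"` labels.
#' @param alpha significance level (default 0.05).
#' @param min_mutated minimum total mutated samples to test a gene.
#' @param classes qualifying variant classes (default non-silent).
#' @return data.frame: `gene`, `a`,`b`,`c`,`d` (mutated-high, wildtype-high,
#'   mutated-low, wildtype-low), `freq_high`, `freq_low`, `odds_ratio`,
#'   `odds_ratio_cc`, `p`, `q`, `direction`
#'   (`"higher_in_low_mg"`/`"higher_in_high_mg"`), `significant`.
#' @export
fisher_gene_screen <- function(records, groups, alpha = 0.05,
                               min_mutated = 3,
                               classes = nonsilent_classes()) {
  labels <- if (inherits(groups, "mg_groups")) groups$labels else groups
  labels <- labels[labels %in% c("High-Mg", "Low-Mg")]
  n_high <- sum(labels == "High-Mg"); n_low <- sum(labels == "Low-Mg")
  if (n_high == 0 || n_low == 0) stopf("both Mg groups must be non-empty")
  samples <- names(labels)
  rec <- filter_classes(records, classes)
  rec <- rec[rec$Tumor_Sample_Barcode %in% samples, , drop = FALSE]
  pairs <- unique(rec[c("Hugo_Symbol", "Tumor_Sample_Barcode")])
  genes <- names(which(table(pairs$Hugo_Symbol) >= min_mutated))
  if (!length(genes))
    return(data.frame(gene = character(0)))
  res <- lapply(genes, function(g) {
    carriers <- pairs$Tumor_Sample_Barcode[pairs$Hugo_Symbol == g]
    a <- sum(labels[carriers] == "High-Mg")
    c_ <- sum(labels[carriers] == "Low-Mg")
    b <- n_high - a; d <- n_low - c_
    ft <- stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))
    or <- (a * d) / (b * c_)
    or_cc <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
    data.frame(gene = g, a = a, b = b, c = c_, d = d,
               freq_high = a / n_high, freq_low = c_ / n_low,
               odds_ratio = or, odds_ratio_cc = or_cc, p = ft$p.value,
               direction = if (c_ / n_low >= a / n_high)
                 "higher_in_low_mg" else "higher_in_high_mg",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bh_adjust(out$p)
  out$significant <- out$p < alpha
  out[order(out$p), ]
}

#' Six-class SNV substitution spectrum
#'
#' Collapses every SNP to the six pyrimidine-referenced substitution
#' classes (C>A, C>G, C>T, T>A, T>C, T>G) by complementing both alleles
#' when the reference base is a purine, and reports class percentages over
#' the classified SNPs. When `groups` is supplied, per-group spectra are
#' returned. Records with ambiguous bases are skipped and counted.
#'
#' @param records a MAF data.frame.
#' @param samples sample ids to include (default: all in records).
#' @param groups optional named label vector (e.g. from [dichotomize_mg()]).
#' @return data.frame with `group` (`"all"` or the label), `class`, `count`,
#'   `pct`; attribute `n_skipped` counts unclassifiable SNPs.
#' @export
snv_class_summary <- function(records, samples = NULL, groups = NULL) {
  samples <- samples %||% unique(records$Tumor_Sample_Barcode)
  snp <- records[records$Variant_Type == "SNP" &
                   records$Tumor_Sample_Barcode %in% samples, , drop = FALSE]
  if (!nrow(snp)) stopf("no SNP records in the sample set")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ref <- snp$Reference_Allele; alt <- snp$Tumor_Seq_Allele2
  valid <- ref %in% names(comp) & alt %in% names(comp)
  n_skipped <- sum(!valid)
  ref <- ref[valid]; alt <- alt[valid]
  flip <- ref %in% c("A", "G")
  ref[flip] <- comp[snp$Reference_Allele[valid][flip]]
  alt[flip] <- comp[snp$Tumor_Seq_Allele2[valid][flip]]
  cls <- factor(paste0(ref, ">", alt),
                levels = c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G"))
  smp <- snp$Tumor_Sample_Barcode[valid]
  one_group <- function(label, keep) {
    tab <- table(cls[keep])
    data.frame(group = label, class = names(tab),
               count = as.integer(tab),
               pct = 100 * as.integer(tab) / max(sum(tab), 1L),
               stringsAsFactors = FALSE)
  }
  out <- one_group("all", rep(TRUE, length(cls)))
  if (!is.null(groups)) {
    labels <- if (inherits(groups, "mg_groups")) groups$labels else groups
    for (lab in sort(unique(labels)))
      out <- rbind(out, one_group(lab, smp %in% names(labels)[labels == lab]))
  }
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Pairwise somatic interactions (co-occurrence / mutual exclusivity)
#'
#' For every unordered pair of the `top_n` most frequently mutated genes,
#' builds the 2x2 sample table (both mutated / only first / only second /
#' neither) and computes the two-sided Fisher exact p-value; odds ratio
#' above 1 is called co-occurrence, below 1 mutual exclusivity. Pairs are
#' flagged at two significance tiers.
#'
#' @param records a MAF data.frame.
#' @param samples sample ids forming the cohort.
#' @param top_n number of top genes by mutation frequency (default 20).
#' @param alpha_strong,alpha_weak significance tiers (default 0.01 / 0.05).
#' @param classes qualifying variant classes (default non-silent).
#' @return data.frame: `gene1`, `gene2`, `both`, `only1`, `only2`,
#'   `neither`, `odds_ratio`, `p`, `direction`, `tier`
#'   (`"strong"`/`"weak"`/`"ns"`).
#' @export
somatic_interactions <- function(records, samples, top_n = 20,
                                 alpha_strong = 0.01, alpha_weak = 0.05,
                                 classes = nonsilent_classes()) {
  freq <- mutation_frequency(records, samples, classes = classes)
  genes <- names(freq)[seq_len(min(top_n, length(freq)))]
  if (length(genes) < 2) stopf("need at least 2 genes after top-n selection")
  rec <- filter_classes(records, classes)
  rec <- rec[rec$Tumor_Sample_Barcode %in% samples, , drop = FALSE]
  mut_in <- lapply(genes, function(g)
    unique(rec$Tumor_Sample_Barcode[rec$Hugo_Symbol == g]))
  names(mut_in) <- genes
  n <- length(samples)
  combos <- utils::combn(genes, 2)
  res <- lapply(seq_len(ncol(combos)), function(i) {
    g1 <- combos[1, i]; g2 <- combos[2, i]
    s1 <- mut_in[[g1]]; s2 <- mut_in[[g2]]
    both <- length(intersect(s1, s2))
    only1 <- length(setdiff(s1, s2)); only2 <- length(setdiff(s2, s1))
    neither <- n - both - only1 - only2
    ft <- stats::fisher.test(matrix(c(both, only1, only2, neither), 2,
                                    byrow = TRUE))
    or <- (both * neither) / (only1 * only2)
    data.frame(gene1 = g1, gene2 = g2, both = both, only1 = only1,
               only2 = only2, neither = neither, odds_ratio = or,
               p = ft$p.value,
               direction = if (is.nan(or) || or > 1) "co-occurrence"
                 else "mutual_exclusivity",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$tier <- ifelse(out$p < alpha_strong, "strong",
                     ifelse(out$p < alpha_weak, "weak", "ns"))
  out
}
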