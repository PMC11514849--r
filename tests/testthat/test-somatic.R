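make_maf_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    gi <- function(i, d) if (length(r) >= i) r[[i]] else d
    data.frame(Hugo_Symbol = r[[1]], Tumor_Sample_Barcode = r[[2]],
               Variant_Classification = r[[3]],
               Variant_Type = gi(4, "SNP"),
               Chromosome = "1", Start_Position = gi(5, 1000L),
               Reference_Allele = gi(6, "C"),
               Tumor_Seq_Allele2 = gi(7, "T"),
               stringsAsFactors = FALSE)
  }))
}

write_maf_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

test_that("MAF reading validates columns, dedups, checks SNP alleles", {
  df <- make_maf_df(
    list("TP53", "s1", "Missense_Mutation", "SNP", 100L),
    list("TP53", "s1", "Missense_Mutation", "SNP", 100L),  # exact dup
    list("APC", "s1", "Nonsense_Mutation", "SNP", 200L),
    list("APC", "s2", "Silent", "SNP", 300L),
    list("KRAS", "s2", "Missense_Mutation", "SNP", 400L))
  maf <- read_maf(write_maf_tsv(df))
  expect_equal(nrow(maf), 4)

  df2 <- df; df2$Variant_Type <- NULL
  expect_error(read_maf(write_maf_tsv(df2)), "Variant_Type")

  df3 <- make_maf_df(list("X", "s1", "Missense_Mutation", "SNP", 1L, "C", "C"))
  expect_error(read_maf(write_maf_tsv(df3)), "SNP")
})

test_that("mutational burden arithmetic and absent samples", {
  df <- do.call(rbind, lapply(1:380, function(i)
    make_maf_df(list("G1", "s1", "Missense_Mutation", "SNP", i))))
  tmb <- compute_tmb(df, samples = c("s1", "s2"), exome_mb = 38)
  expect_equal(unname(tmb), c(10, 0))
})

test_that("hypermutation exclusion requires both burden and an MMR hit", {
  mk_many <- function(smp, n, gene = "G1") do.call(rbind, lapply(seq_len(n),
    function(i) make_maf_df(list(gene, smp, "Missense_Mutation", "SNP",
                                 as.integer(i)))))
  df <- rbind(
    mk_many("hyper_mmr", 400),
    make_maf_df(list("MLH1", "hyper_mmr", "Missense_Mutation", "SNP", 9991L)),
    mk_many("hyper_clean", 400, "G2"),
    make_maf_df(list("POLE", "calm", "Missense_Mutation", "SNP", 9992L)),
    # a hypermutated sample whose MMR hit is Silent does not trigger
    mk_many("hyper_silent", 400, "G3"),
    make_maf_df(list("MSH2", "hyper_silent", "Silent", "SNP", 9993L)))
  hf <- hypermutation_filter(df, exome_mb = 38)
  expect_equal(hf$excluded$sample, "hyper_mmr")
  expect_match(hf$excluded$trigger, "MLH1")
  expect_setequal(hf$retained, c("hyper_clean", "calm", "hyper_silent"))
  expect_equal(hf$n_hypermutated, 3)
  # never removes a sample at or below the threshold
  expect_true(all(hf$tmb[hf$excluded$sample] > 10))
})

test_that("gene-size filter removes >= 5000 aa strictly", {
  df <- make_maf_df(
    list("SMALL", "s1", "Missense_Mutation", "SNP", 1L),
    list("EDGE", "s1", "Missense_Mutation", "SNP", 2L),
    list("UNDER", "s1", "Missense_Mutation", "SNP", 3L),
    list("UNKNOWN", "s1", "Missense_Mutation", "SNP", 4L))
  len <- data.frame(gene = c("SMALL", "EDGE", "UNDER"),
                    aa_length = c(500L, 5000L, 4999L))
  out <- gene_size_filter(df, len)
  expect_setequal(out$Hugo_Symbol, c("SMALL", "UNDER", "UNKNOWN"))
  expect_equal(attr(out, "unmapped_genes"), "UNKNOWN")
  # the shipped annotation drops a titin-like giant gene
  ship <- default_gene_lengths()
  df2 <- make_maf_df(list("TTN", "s1", "Missense_Mutation", "SNP", 1L),
                     list("TP53", "s1", "Missense_Mutation", "SNP", 2L))
  expect_equal(gene_size_filter(df2, ship)$Hugo_Symbol, "TP53")
})

test_that("mutation frequency counts samples, not records", {
  df <- make_maf_df(
    list("TP53", "s1", "Missense_Mutation", "SNP", 1L),
    list("TP53", "s1", "Nonsense_Mutation", "SNP", 2L),  # same sample twice
    list("TP53", "s2", "Missense_Mutation", "SNP", 3L),
    list("APC", "s3", "Silent", "SNP", 4L))
  freq <- mutation_frequency(df, samples = c("s1", "s2", "s3", "s4"))
  expect_equal(unname(freq["TP53"]), 0.5)
  expect_false("APC" %in% names(freq))  # silent does not qualify
  expect_equal(unname(mutation_frequency(df, c("s1", "s2"))["TP53"]), 1)
})

test_that("per-gene Fisher screen matches enumeration and inverts cleanly", {
  # exhaustive fixed-margin oracle over a grid of tables
  set.seed(31)
  for (i in 1:25) {
    a <- sample(0:12, 1); b <- sample(0:12, 1)
    c_ <- sample(0:12, 1); d <- sample(0:12, 1)
    if ((a + c_) == 0 || (b + d) == 0) next
    p_pkg <- fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))$p.value
    expect_equal(p_pkg, fisher_oracle(a, b, c_, d), tolerance = 1e-9,
                 label = sprintf("table (%d,%d,%d,%d)", a, b, c_, d))
  }

  labels <- setNames(rep(c("High-Mg", "Low-Mg"), c(10, 10)),
                     sprintf("s%02d", 1:20))
  df <- do.call(rbind, lapply(sprintf("s%02d", c(1:8, 11:12)), function(s)
    make_maf_df(list("GENEA", s, "Missense_Mutation", "SNP",
                     sample.int(1e6, 1)))))
  scr <- fisher_gene_screen(df, labels)
  expect_equal(scr$a, 8); expect_equal(scr$c, 2)
  expect_equal(scr$p, fisher.test(matrix(c(8, 2, 2, 8), 2))$p.value)
  expect_equal(scr$direction, "higher_in_high_mg")

  # swapping the group labels inverts the odds ratio, p unchanged
  flipped <- setNames(ifelse(labels == "High-Mg", "Low-Mg", "High-Mg"),
                      names(labels))
  scr2 <- fisher_gene_screen(df, flipped)
  expect_equal(scr2$p, scr$p)
  expect_equal(scr2$odds_ratio, 1 / scr$odds_ratio)

  # identical frequencies in both groups: p = 1
  df_eq <- do.call(rbind, lapply(sprintf("s%02d", c(1:5, 11:15)), function(s)
    make_maf_df(list("GENEB", s, "Missense_Mutation", "SNP",
                     sample.int(1e6, 1)))))
  expect_equal(fisher_gene_screen(df_eq, labels)$p, 1)
})

test_that("SNV classes collapse to the pyrimidine strand and sum to 100%", {
  df <- make_maf_df(
    list("G", "s1", "Missense_Mutation", "SNP", 1L, "A", "G"),  # -> T>C
    list("G", "s1", "Missense_Mutation", "SNP", 2L, "C", "T"),  # -> C>T
    list("G", "s1", "Missense_Mutation", "SNP", 3L, "G", "T"),  # -> C>A
    list("G", "s1", "Missense_Mutation", "SNP", 4L, "T", "C"),  # -> T>C
    list("G", "s1", "Missense_Mutation", "SNP", 5L, "N", "A"),  # skipped
    list("G", "s1", "Frame_Shift_Del", "DEL", 6L, "TG", "-"))   # not a SNP
  s <- snv_class_summary(df)
  get <- function(cl) s$count[s$group == "all" & s$class == cl]
  expect_equal(get("T>C"), 2)
  expect_equal(get("C>T"), 1)
  expect_equal(get("C>A"), 1)
  expect_equal(sum(s$pct[s$group == "all"]), 100)
  expect_equal(attr(s, "n_skipped"), 1)
})

test_that("planted SNV spectrum difference is recovered per Mg group", {
  b <- small_cohort()
  groups <- setNames(
    ifelse(b$clinical$mg < b$truth$mg_cutpoint, "Low-Mg", "High-Mg"),
    b$clinical$tumor_sample)
  s <- snv_class_summary(b$maf, groups = groups)
  tc_low <- s$pct[s$group == "Low-Mg" & s$class == "T>C"]
  tc_high <- s$pct[s$group == "High-Mg" & s$class == "T>C"]
  expect_gt(tc_low, tc_high)  # T>C planted dominant in Low-Mg
  expect_equal(tc_low, 100 * b$truth$snv_spectrum$low_mg[["T>C"]],
               tolerance = 0.15)
})

test_that("somatic interactions detect co-occurrence and exclusivity", {
  samples <- sprintf("s%02d", 1:30)
  # G1 and G2 mutated in identical samples; G3 disjoint from both
  df <- rbind(
    do.call(rbind, lapply(samples[1:12], function(s) rbind(
      make_maf_df(list("G1", s, "Missense_Mutation", "SNP",
                       sample.int(1e6, 1))),
      make_maf_df(list("G2", s, "Missense_Mutation", "SNP",
                       sample.int(1e6, 1)))))),
    do.call(rbind, lapply(samples[13:30], function(s)
      make_maf_df(list("G3", s, "Missense_Mutation", "SNP",
                       sample.int(1e6, 1))))))
  si <- somatic_interactions(df, samples, top_n = 3)
  pair <- function(g1, g2) si[(si$gene1 == g1 & si$gene2 == g2) |
                                (si$gene1 == g2 & si$gene2 == g1), ]
  expect_equal(pair("G1", "G2")$direction, "co-occurrence")
  expect_lt(pair("G1", "G2")$p, 0.01)
  expect_equal(pair("G1", "G3")$direction, "mutual_exclusivity")
  expect_lt(pair("G1", "G3")$p, 0.01)
  expect_equal(pair("G1", "G2")$both +
                 pair("G1", "G2")$only1 + pair("G1", "G2")$only2 +
                 pair("G1", "G2")$neither, 30)
})
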