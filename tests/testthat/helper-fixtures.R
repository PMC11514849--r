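# fixtures shared across test files; everything is built in code

# a raw quant table with explicit values (kind = "protein" by default)
make_quant <- function(values, is = NULL, kind = "protein",
                       unique_peptides = NULL, loc_prob = NULL,
                       batch = "B1") {
  values <- as.matrix(values)
  nr <- nrow(values)
  if (is.null(rownames(values))) rownames(values) <- sprintf("F%02d", 1:nr)
  if (is.null(colnames(values))) colnames(values) <- sprintf("S%02d",
                                                             1:ncol(values))
  is <- is %||% rowMeans(values)
  ints <- cbind(IS = is, values)
  meta <- if (kind == "protein") {
    data.frame(Protein = rownames(values),
               Unique_Peptides = unique_peptides %||% rep(3L, nr),
               Contaminant = "", Reverse = "", stringsAsFactors = FALSE)
  } else {
    data.frame(Site = rownames(values),
               Parent_Protein = sub("_S[0-9]+$", "", rownames(values)),
               Localization_Prob = loc_prob %||% rep(0.95, nr),
               Contaminant = "", Reverse = "", stringsAsFactors = FALSE)
  }
  structure(list(intensities = ints, meta = meta, kind = kind, batch = batch,
                 is_channel = "IS", stage = "raw"),
            class = "mg_quant")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# write a quant table in the on-disk dialect
write_quant_tsv <- function(tab, path) {
  df <- cbind(tab$meta, as.data.frame(tab$intensities))
  names(df)[-seq_len(ncol(tab$meta))] <-
    paste0("Intensity_", colnames(tab$intensities))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# a small cohort used by several files (cached per session)
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_cohort(cohort_config(
        n_patients = 40, n_batches = 10, plex_size = 9, n_proteins = 300,
        n_phosphosites = 80, n_genes = 60, seed = 101))
    cache
  }
})

# run the ingest chain over a written cohort directory
ingest_cohort_proteins <- function(bundle, dir = tempfile()) {
  write_cohort(bundle, dir, overwrite = TRUE)
  mats <- lapply(names(bundle$batches), function(b)
    bridge_to_is(scale_total_intensity(filter_features(
      read_quant_table(file.path(dir, sprintf("%s_proteins.tsv", b)),
                       "protein")))))
  filter_missing(zscore(combine_batches(mats)))
}

# brute-force oracles -------------------------------------------------------

# two-sided Fisher exact p by enumerating every table with fixed margins
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- vapply(lo:hi, function(x)
    exp(lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)), numeric(1))
  sum(probs[probs <= probs[a - lo + 1] * (1 + 1e-7)])
}

# two-sided Wilcoxon rank-sum p by enumerating every group assignment
wilcox_oracle <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  nx <- length(x)
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- combn(length(pooled), nx)
  w_all <- apply(combs, 2, function(ix) sum(r[ix]) - nx * (nx + 1) / 2)
  mu <- mean(w_all)
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# two-sided Spearman p by enumerating all n! permutations
spearman_oracle <- function(x, y) {
  n <- length(x)
  perms <- mgscreen:::all_perms(n)
  rx <- rank(x); ry <- rank(y)
  rho_obs <- cor(rx, ry)
  rho_all <- apply(perms, 1, function(ix) cor(rx, ry[ix]))
  mean(abs(rho_all) >= abs(rho_obs) - 1e-12)
}
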