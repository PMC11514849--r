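#' Read a batched quantification table
#'
#' Parses one batch of the simplified tab-separated quantification dialect
#' (one row per protein or phosphosite, channel intensities in
#' `Intensity_<sample>` columns plus an `Intensity_IS` internal-standard
#' column, MaxQuant-style `+` flags for contaminant and reverse hits).
#' Flagged rows are removed on read; zero intensity means "not observed".
#'
#' Required metadata columns: proteins need `Protein` and `Unique_Peptides`;
#' phosphosites need `Site`, `Parent_Protein` and `Localization_Prob`. Both
#' kinds need `Contaminant` and `Reverse`. Unknown columns are ignored with
#' a warning.
#'
#' @param path path to the TSV file.
#' @param kind `"protein"` or `"phospho"`.
#' @param batch batch id; defaults to the file name stem.
#' @param is_channel name of the internal-standard channel (the intensity
#'   column is `Intensity_<is_channel>`).
#' @return an `mg_quant` table: `intensities` (features x channels, IS
#'   included), `meta` (per-row metadata), `kind`, `batch`, `is_channel`,
#'   `stage` (`"raw"`).
#' @export
read_quant_table <- function(path, kind = c("protein", "phospho"),
                             batch = NULL, is_channel = "IS") {
  kind <- match.arg(kind)
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  id_col <- if (kind == "protein") "Protein" else "Site"
  meta_cols <- if (kind == "protein") {
    c("Protein", "Unique_Peptides", "Contaminant", "Reverse")
  } else {
    c("Site", "Parent_Protein", "Localization_Prob", "Contaminant", "Reverse")
  }
  missing_meta <- setdiff(meta_cols, names(raw))
  if (length(missing_meta))
    stopf("missing required column(s): %s", paste(missing_meta,
                                                  collapse = ", "))
  int_cols <- grep("^Intensity_", names(raw), value = TRUE)
  if (!length(int_cols)) stopf("no Intensity_* channel columns found")
  unknown <- setdiff(names(raw), c(meta_cols, int_cols))
  if (length(unknown))
    warnf("ignoring unknown column(s): %s", paste(unknown, collapse = ", "))

  is_col <- paste0("Intensity_", is_channel)
  if (!is_col %in% int_cols)
    stopf("internal-standard channel '%s' not found (no column %s)",
          is_channel, is_col)

  parse_num <- function(col, nm) {
    v <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(v) & !(is.na(col) | col == "" | col == "NA"))
    if (length(bad))
      stopf("malformed numeric in column '%s', row %d: '%s'",
            nm, bad[1], col[bad[1]])
    v
  }
  ints <- vapply(int_cols, function(nm) parse_num(raw[[nm]], nm),
                 numeric(nrow(raw)))
  ints <- matrix(ints, nrow = nrow(raw),
                 dimnames = list(raw[[id_col]], sub("^Intensity_", "",
                                                    int_cols)))
  if (any(ints < 0, na.rm = TRUE)) stopf("negative intensities found")
  ints[is.na(ints)] <- 0

  meta <- raw[meta_cols]
  if (kind == "protein")
    meta$Unique_Peptides <- as.integer(parse_num(meta$Unique_Peptides,
                                                 "Unique_Peptides"))
  if (kind == "phospho")
    meta$Localization_Prob <- parse_num(meta$Localization_Prob,
                                        "Localization_Prob")

  keep <- !(meta$Contaminant %in% "+" | meta$Reverse %in% "+")
  ints <- ints[keep, , drop = FALSE]
  meta <- meta[keep, , drop = FALSE]
  rownames(meta) <- NULL

  structure(
    list(intensities = ints, meta = meta, kind = kind,
         batch = batch %||% sub("\\.[^.]*$", "", basename(path)),
         is_channel = is_channel, stage = "raw"),
    class = "mg_quant"
  )
}

#' @export
print.mg_quant <- function(x, ...) {
  cat(sprintf("<mg_quant:%s> %d features x %d channels (IS: %s) | batch %s | stage %s\n",
              x$kind, nrow(x$intensities), ncol(x$intensities), x$is_channel,
              x$batch, x$stage))
  invisible(x)
}

#' Apply the identification-quality feature filters
#'
#' Proteins are kept when supported by at least 2 unique peptides;
#' phosphosites are kept when the localization probability is strictly
#' greater than 0.75 (a site at exactly 0.75 is dropped).
#'
#' @param table an `mg_quant` from [read_quant_table()].
#' @param min_unique_peptides protein filter threshold (kept when `>=`).
#' @param min_localization phosphosite filter threshold (kept when `>`).
#' @return the filtered `mg_quant`.
#' @export
filter_features <- function(table, min_unique_peptides = 2,
                            min_localization = 0.75) {
  if (!inherits(table, "mg_quant")) stopf("'table' must be an mg_quant")
  keep <- if (table$kind == "protein") {
    table$meta$Unique_Peptides >= min_unique_peptides
  } else {
    table$meta$Localization_Prob > min_localization
  }
  table$intensities <- table$intensities[keep, , drop = FALSE]
  table$meta <- table$meta[keep, , drop = FALSE]
  rownames(table$meta) <- NULL
  table
}

#' Equalize total intensity across channels of a batch
#'
#' Each channel (IS included) is multiplied by a scalar so that its sum over
#' observed (nonzero) values equals the pre-scaling mean of the channel sums.
#' Zeros stay zero: a zero intensity is a non-detection, not a measurement.
#'
#' @param table an `mg_quant` at stage `"raw"`.
#' @return the `mg_quant` at stage `"scaled"`.
#' @export
scale_total_intensity <- function(table) {
  if (!inherits(table, "mg_quant")) stopf("'table' must be an mg_quant")
  if (table$stage != "raw") stopf("scale_total_intensity() needs stage 'raw'")
  sums <- colSums(table$intensities)
  if (any(sums == 0))
    stopf("all-zero channel(s): %s",
          paste(colnames(table$intensities)[sums == 0], collapse = ", "))
  table$intensities <- sweep(table$intensities, 2, mean(sums) / sums, `*`)
  table$stage <- "scaled"
  table
}

#' Bridge a batch to its internal-standard channel
#'
#' Divides every sample channel row-wise by the internal-standard (IS)
#' channel, yielding sample-to-standard (S/S) values that are comparable
#' across batches. Zeros (non-detections) become missing before the ratio;
#' a row whose IS value is zero becomes missing for every sample of the
#' batch. The IS channel is removed from the output.
#'
#' @param table an `mg_quant` at stage `"scaled"`.
#' @return an [expression_matrix()] at stage `"s_over_s"`.
#' @export
bridge_to_is <- function(table) {
  if (!inherits(table, "mg_quant")) stopf("'table' must be an mg_quant")
  if (table$stage != "scaled") stopf("bridge_to_is() needs stage 'scaled'")
  ints <- table$intensities
  ints[ints == 0] <- NA_real_
  is_vals <- ints[, table$is_channel]
  samp <- ints[, setdiff(colnames(ints), table$is_channel), drop = FALSE]
  ratio <- samp / is_vals  # NA IS value wipes the row
  batch_map <- stats::setNames(rep(table$batch, ncol(ratio)), colnames(ratio))
  expression_matrix(ratio, stage = "s_over_s", batch = batch_map,
                    note = sprintf("batch %s bridged to IS channel '%s'",
                                   table$batch, table$is_channel))
}

#' Combine bridged batches into one matrix
#'
#' Outer join on feature ids across batches; features absent from a batch are
#' missing for that batch's samples. If inputs are at stage `"s_over_s"` the
#' combined matrix is log2-transformed.
#'
#' @param matrices list of [expression_matrix()] objects at stage
#'   `"s_over_s"` (or `"log2"`).
#' @return an [expression_matrix()] at stage `"log2"` with the batch map
#'   retained.
#' @export
combine_batches <- function(matrices) {
  if (!length(matrices)) stopf("no matrices to combine")
  stages <- vapply(matrices, function(m) {
    require_stage(m, c("s_over_s", "log2"), "combine_batches"); m$stage
  }, character(1))
  if (length(unique(stages)) > 1)
    stopf("all batches must be at the same stage")
  samples <- unlist(lapply(matrices, function(m) colnames(m$values)))
  if (anyDuplicated(samples))
    stopf("duplicate sample id(s) across batches: %s",
          paste(unique(samples[duplicated(samples)]), collapse = ", "))
  features <- unique(unlist(lapply(matrices, function(m)
    rownames(m$values))))
  out <- matrix(NA_real_, length(features), length(samples),
                dimnames = list(features, samples))
  batch_map <- character(0)
  for (m in matrices) {
    out[rownames(m$values), colnames(m$values)] <- m$values
    batch_map <- c(batch_map, m$batch)
  }
  if (stages[1] == "s_over_s") out <- log2(out)
  expression_matrix(out, stage = "log2", batch = batch_map,
                    note = sprintf("%d batches combined; log2(S/S)",
                                   length(matrices)))
}

#' Dual z-scoring of a combined matrix
#'
#' Standardizes the matrix along one or both axes over observed entries.
#' The default applies column (sample) z-scores first and row (feature)
#' z-scores second; the order is configurable and recorded in the matrix
#' provenance note. An axis vector with fewer than 2 observed values or zero
#' variance becomes all-missing.
#'
#' @param matrix an [expression_matrix()] at stage `"log2"`.
#' @param axes character vector, a sequence drawn from
#'   `"columns"`/`"rows"`, applied in order.
#' @return an [expression_matrix()] at stage `"zscore"`.
#' @export
zscore <- function(matrix, axes = c("columns", "rows")) {
  require_stage(matrix, "log2", "zscore")
  axes <- match.arg(axes, c("columns", "rows"), several.ok = TRUE)
  v <- matrix$values
  z1 <- function(x) {
    ok <- !is.na(x)
    if (sum(ok) < 2) return(rep(NA_real_, length(x)))
    s <- stats::sd(x[ok])
    if (!is.finite(s) || s == 0) return(rep(NA_real_, length(x)))
    (x - mean(x[ok])) / s
  }
  for (ax in axes) {
    v <- if (ax == "columns") apply(v, 2, z1) else t(apply(v, 1, z1))
  }
  dimnames(v) <- dimnames(matrix$values)
  out <- advance_stage(matrix, "zscore",
                       note = paste("z-scored:", paste(axes, collapse = " then ")))
  out$values <- v
  out
}

#' Drop features with excessive missingness
#'
#' Removes rows whose missing fraction is strictly greater than
#' `max_missing_frac`; a feature missing in exactly half the samples is
#' retained at the default. Idempotent.
#'
#' @param matrix an [expression_matrix()].
#' @param max_missing_frac maximum tolerated missing fraction (default 0.5).
#' @return the filtered [expression_matrix()].
#' @export
filter_missing <- function(matrix, max_missing_frac = 0.5) {
  if (!inherits(matrix, "mg_expr")) stopf("'matrix' must be an mg_expr")
  frac <- rowMeans(is.na(matrix$values))
  keep <- frac <= max_missing_frac
  matrix$values <- matrix$values[keep, , drop = FALSE]
  matrix$note <- c(matrix$note,
                   sprintf("filter_missing(%.2f): %d of %d rows kept",
                           max_missing_frac, sum(keep), length(keep)))
  matrix
}

#' Wilcoxon rank-sum differential abundance
#'
#' Per-feature two-sided Wilcoxon rank-sum test between two sample groups on
#' a log2-scale matrix (exact for small samples without ties, normal
#' approximation with tie correction otherwise), with the effect reported as
#' the median log2 fold change: the median over pairs of within-pair
#' differences when `paired = TRUE` (groups aligned by position), else the
#' difference of group medians.
#'
#' @param matrix an [expression_matrix()] at stage `"log2"` or `"zscore"`.
#' @param group_a,group_b disjoint character vectors of sample ids; when
#'   `paired = TRUE` they must be equal-length and pair-aligned.
#' @param paired treat groups as paired samples for the effect size.
#' @return data.frame with `feature`, `p`, `effect`, `n_a`, `n_b`, `tested`,
#'   `reason` (why a feature was skipped, `NA` otherwise).
#' @export
differential_abundance <- function(matrix, group_a, group_b, paired = FALSE) {
  require_stage(matrix, c("log2", "zscore"), "differential_abundance")
  if (!length(group_a) || !length(group_b)) stopf("empty group")
  if (length(intersect(group_a, group_b))) stopf("groups must be disjoint")
  miss <- setdiff(c(group_a, group_b), colnames(matrix$values))
  if (length(miss)) stopf("sample(s) not in matrix: %s",
                          paste(miss, collapse = ", "))
  if (paired && length(group_a) != length(group_b))
    stopf("paired groups must have equal length")
  v <- matrix$values
  res <- lapply(rownames(v), function(f) {
    a <- v[f, group_a]; b <- v[f, group_b]
    if (paired) {
      d <- a - b
      eff <- stats::median(d, na.rm = TRUE)
    } else {
      eff <- stats::median(a, na.rm = TRUE) - stats::median(b, na.rm = TRUE)
    }
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2 || length(b) < 2)
      return(data.frame(feature = f, p = NA_real_, effect = NA_real_,
                        n_a = length(a), n_b = length(b), tested = FALSE,
                        reason = "fewer than 2 observed values in a group",
                        stringsAsFactors = FALSE))
    p <- suppressWarnings(stats::wilcox.test(a, b, exact = NULL)$p.value)
    data.frame(feature = f, p = p, effect = eff,
               n_a = length(a), n_b = length(b), tested = TRUE,
               reason = NA_character_, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Flag features by the cell-experiment differential rule
#'
#' A feature is flagged when its treated/control abundance ratio is above
#' `up` or below `down` and its p-value is below `alpha`
#' (defaults 1.2 / 0.83 / 0.05).
#'
#' @param ratio numeric vector of abundance ratios (treated / control).
#' @param p numeric vector of p-values, same length.
#' @param up,down ratio bounds; `alpha` significance bound.
#' @return logical vector.
#' @export
flag_cell_differential <- function(ratio, p, up = 1.2, down = 0.83,
                                   alpha = 0.05) {
  if (length(ratio) != length(p)) stopf("'ratio' and 'p' lengths differ")
  (ratio > up | ratio < down) & p < alpha
}
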