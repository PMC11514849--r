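# Local preranked GSEA (weighted Kolmogorov-Smirnov running sum with
# gene-label permutation) and hypergeometric over-representation analysis.

#' Read gene sets from a GMT file
#'
#' Tab-separated: set name, description, then members. Duplicate members
#' within a set are deduplicated.
#'
#' @param path path to the GMT file.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3)
      stopf("malformed GMT line %d: fewer than 3 tab-separated fields", i)
    sets[[parts[1]]] <- unique(parts[-(1:2)])
  }
  sets
}

# enrichment score of one hit-index set against a descending-ranked list;
# returns c(es, peak_index) where peak_index locates the extremum
gsea_es <- function(abs_scores_w, idx, N) {
  nh <- length(idx)
  wgt <- unname(abs_scores_w[idx])
  nr <- sum(wgt)
  if (nr == 0) wgt[] <- 1 / nh else wgt <- wgt / nr
  pm <- 1 / (N - nh)
  cumw <- cumsum(wgt)
  miss_before <- (idx - seq_len(nh)) * pm
  top <- cumw - miss_before          # running sum right after each hit
  bottom <- top - wgt                # running sum just before each hit
  m1 <- max(top); m2 <- min(bottom)
  if (m1 >= -m2) c(m1, which.max(top)) else c(m2, which.min(bottom))
}

#' Preranked gene-set enrichment analysis
#'
#' Weighted Kolmogorov-Smirnov running-sum enrichment on a preranked list:
#' walking down the list, hits increment the sum by `|score|^weight`
#' (normalized over the set's hits) and misses decrement it by
#' `1/(N - set size)`; the enrichment score (ES) is the maximum deviation.
#' The null distribution is generated by gene-label permutation (random hit
#' sets of the same size); NES divides ES by the mean same-sign null |ES|,
#' the nominal p is the same-sign null tail, and FDR q-values follow the
#' convention of pooling positively and negatively scoring sets separately
#' over the set-wise normalized null.
#'
#' @param scores named numeric vector of ranking scores (e.g. Spearman rho
#'   against Mg content); sorted descending internally; ids must be unique.
#' @param sets named list of member vectors (see [read_gmt()]).
#' @param weight exponent on |score| for hit increments (default 1;
#'   0 gives the unweighted Kolmogorov-Smirnov statistic).
#' @param n_perm permutations for the null (default 1000).
#' @param min_size,max_size set-size bounds after intersection with the
#'   ranked list (default 5 / 500).
#' @param seed optional seed for the permutation draw.
#' @return data.frame: `set`, `size`, `es`, `nes`, `p`, `q`,
#'   `leading_edge` (comma-joined ids), plus a `skipped` attribute naming
#'   sets outside the size bounds.
#' @export
preranked_gsea <- function(scores, sets, weight = 1, n_perm = 1000,
                           min_size = 5, max_size = 500, seed = NULL) {
  if (is.null(names(scores))) stopf("'scores' must be named")
  if (anyDuplicated(names(scores))) stopf("duplicate ids in 'scores'")
  if (anyNA(scores)) {
    scores <- scores[!is.na(scores)]
  }
  ord <- order(scores, decreasing = TRUE)
  scores <- scores[ord]
  ids <- names(scores)
  N <- length(scores)
  asw <- abs(scores)^weight
  if (!is.null(seed)) set.seed(seed)

  hit_idx <- lapply(sets, function(m) which(ids %in% m))
  sizes <- vapply(hit_idx, length, integer(1))
  usable <- sizes >= min_size & sizes <= max_size & sizes < N
  skipped <- names(sets)[!usable]
  hit_idx <- hit_idx[usable]
  sizes <- sizes[usable]
  if (!length(hit_idx)) {
    out <- data.frame(set = character(0))
    attr(out, "skipped") <- skipped
    return(out)
  }

  obs <- vapply(hit_idx, function(ix) gsea_es(asw, sort(ix), N), numeric(2))
  es <- obs[1, ]; peak <- obs[2, ]

  # one permutation block per distinct set size
  null_by_size <- lapply(unique(sizes), function(sz) {
    vapply(seq_len(n_perm), function(i)
      gsea_es(asw, sort(sample.int(N, sz)), N)[1], numeric(1))
  })
  names(null_by_size) <- as.character(unique(sizes))

  res <- lapply(seq_along(hit_idx), function(j) {
    nm <- names(hit_idx)[j]
    null_es <- null_by_size[[as.character(sizes[j])]]
    same <- null_es[sign(null_es) == sign(es[j])]
    mean_same <- mean(abs(same))
    nes <- if (length(same) && mean_same > 0) es[j] / mean_same else NA_real_
    p <- if (length(same))
      (1 + sum(abs(same) >= abs(es[j]) - 1e-12)) / (1 + length(same))
      else 1
    ix <- sort(hit_idx[[j]])
    le <- if (es[j] >= 0) ids[ix[seq_len(peak[j])]]
      else ids[ix[seq(peak[j], length(ix))]]
    data.frame(set = nm, size = sizes[j], es = es[j], nes = nes, p = p,
               leading_edge = paste(le, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)

  # FDR: pool set-wise normalized null NES, split by sign
  null_nes <- unlist(lapply(seq_along(hit_idx), function(j) {
    null_es <- null_by_size[[as.character(sizes[j])]]
    pos <- null_es[null_es >= 0]; neg <- null_es[null_es < 0]
    c(if (length(pos) && mean(pos) > 0) pos / mean(pos),
      if (length(neg) && mean(abs(neg)) > 0) neg / mean(abs(neg)))
  }))
  out$q <- vapply(seq_len(nrow(out)), function(j) {
    nes <- out$nes[j]
    if (is.na(nes)) return(NA_real_)
    if (nes >= 0) {
      null_tail <- mean(null_nes[null_nes >= 0] >= nes)
      obs_tail <- mean(out$nes[out$nes >= 0 & !is.na(out$nes)] >= nes)
    } else {
      null_tail <- mean(null_nes[null_nes < 0] <= nes)
      obs_tail <- mean(out$nes[out$nes < 0 & !is.na(out$nes)] <= nes)
    }
    if (obs_tail == 0) return(NA_real_)
    min(null_tail / obs_tail, 1)
  }, numeric(1))
  attr(out, "skipped") <- skipped
  out[order(out$p), ]
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test of the overlap between a hit list and each
#' gene set (both intersected with the background), with Benjamini-Hochberg
#' q-values. A local replacement for web-service enrichment tools.
#'
#' @param hits character vector of significant features (subset of
#'   `background`).
#' @param background character vector: the tested universe.
#' @param sets named list of member vectors.
#' @param min_overlap_set sets with no member in the background are skipped.
#' @return data.frame: `set`, `set_size` (in background), `overlap`, `p`,
#'   `q`, `members` (overlapping ids, comma-joined); attribute `skipped`.
#' @export
ora_hypergeom <- function(hits, background, sets, min_overlap_set = 1) {
  if (!length(hits)) stopf("empty hit list")
  background <- unique(background)
  hits <- unique(hits)
  if (!all(hits %in% background))
    stopf("hits must be a subset of the background")
  res <- list(); skipped <- character(0)
  for (nm in names(sets)) {
    m <- intersect(sets[[nm]], background)
    if (length(m) < min_overlap_set) {
      skipped <- c(skipped, nm)
      next
    }
    k <- length(intersect(hits, m))
    p <- stats::phyper(k - 1, length(m), length(background) - length(m),
                       length(hits), lower.tail = FALSE)
    res[[nm]] <- data.frame(set = nm, set_size = length(m), overlap = k,
                            p = p,
                            members = paste(intersect(hits, m),
                                            collapse = ","),
                            stringsAsFactors = FALSE)
  }
  if (!length(res)) {
    out <- data.frame(set = character(0))
  } else {
    out <- do.call(rbind, res)
    out$q <- bh_adjust(out$p)
    out <- out[order(out$p), c("set", "set_size", "overlap", "p", "q",
                               "members")]
  }
  attr(out, "skipped") <- skipped
  rownames(out) <- NULL
  out
}
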