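# --- Spearman correlation with exact small-sample permutation p ------------

# all permutations of 1..n as an (n!) x n integer matrix
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  p <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, p + (p >= i))
  }))
}

#' Spearman rank correlation test
#'
#' Spearman's rho with average ranks for ties. The two-sided p-value is
#' computed by exhaustive permutation enumeration for `n <= exact_max`
#' (valid with ties), and otherwise by the t approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors; incomplete pairs are dropped.
#' @param exact_max largest n for exhaustive enumeration (default 9).
#' @return list with `rho`, `p`, `n`, `method`.
#' @export
spearman_test <- function(x, y, exact_max = 9L) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) return(list(rho = NA_real_, p = NA_real_, n = n,
                         method = "untested"))
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n, method = "constant"))
  rho <- stats::cor(rx, ry)
  if (n <= exact_max) {
    perms <- all_perms(n)
    ry_mat <- matrix(ry[perms], nrow(perms), n)
    s <- as.numeric(ry_mat %*% rx)
    rho_perm <- (s / n - mean(rx) * mean(ry)) /
      (stats::sd(rx) * stats::sd(ry) * (n - 1) / n)
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact_permutation"
  } else {
    if (abs(rho) >= 1 - 1e-12) {
      p <- 2e-16
    } else {
      tt <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tt), df = n - 2)
    }
    method <- "t_approximation"
  }
  list(rho = rho, p = max(p, .Machine$double.xmin), n = n, method = method)
}

#' Screen features for correlation with Mg content
#'
#' Per-feature Spearman correlation between the expression matrix rows and
#' the Mg content of the same samples, on pairwise-complete observations.
#' Features with fewer than `min_pairs` complete pairs (or constant over
#' them) are reported untested. Raw p-values are the screening criterion,
#' matching the source convention; Benjamini-Hochberg q-values are reported
#' alongside.
#'
#' @param matrix an [expression_matrix()] (any stage with defined values).
#' @param mg named numeric vector of Mg content (ug per g protein); names are
#'   sample ids, matched against the matrix columns.
#' @param alpha significance level partitioning the screen (default 0.05).
#' @param min_pairs minimum complete pairs to test a feature (default 10).
#' @param stratum label stored in the results (default `"all"`).
#' @return data.frame with `feature`, `rho`, `p`, `q`, `n`, `direction`
#'   (`"positive"`/`"negative"`), `significant` (p < alpha), `tested`,
#'   `reason`, `stratum`.
#' @export
spearman_screen <- function(matrix, mg, alpha = 0.05, min_pairs = 10,
                            stratum = "all") {
  if (!inherits(matrix, "mg_expr")) stopf("'matrix' must be an mg_expr")
  if (is.null(names(mg))) stopf("'mg' must be a named vector of sample ids")
  samples <- intersect(colnames(matrix$values), names(mg))
  if (length(samples) < min_pairs)
    stopf("only %d samples have both expression and Mg content (need %d)",
          length(samples), min_pairs)
  v <- matrix$values[, samples, drop = FALSE]
  mgv <- mg[samples]
  res <- lapply(rownames(v), function(f) {
    ts <- spearman_test(v[f, ], mgv)
    tested <- ts$n >= min_pairs && ts$method %in%
      c("exact_permutation", "t_approximation")
    reason <- if (tested) NA_character_
      else if (ts$n < min_pairs) sprintf("only %d complete pairs", ts$n)
      else "constant over complete pairs"
    data.frame(feature = f,
               rho = if (tested) ts$rho else NA_real_,
               p = if (tested) ts$p else NA_real_,
               n = ts$n,
               direction = if (tested && !is.na(ts$rho))
                 c("negative", "positive")[(ts$rho >= 0) + 1L]
                 else NA_character_,
               tested = tested, reason = reason,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- NA_real_
  out$q[out$tested] <- bh_adjust(out$p[out$tested])
  out$significant <- out$tested & out$p < alpha
  out$stratum <- stratum
  out[c("feature", "rho", "p", "q", "n", "direction", "significant",
        "tested", "reason", "stratum")]
}

#' Side-stratified Mg screen with overlap sets
#'
#' Runs [spearman_screen()] separately inside each stratum (e.g., left- and
#' right-sided tumors) and summarizes the overlap of significant features
#' between the two strata per direction: shared, first-only, second-only.
#' Strata with fewer than `min_pairs` samples are skipped and reported.
#'
#' @param matrix an [expression_matrix()].
#' @param mg named numeric Mg vector (see [spearman_screen()]).
#' @param strata named character vector, sample id -> stratum label
#'   (exactly two distinct labels among the usable samples).
#' @inheritParams spearman_screen
#' @return list with `results` (named list of per-stratum screen tables),
#'   `overlap` (per direction: ids and counts of `both` / `<label>_only`),
#'   and `skipped` (labels of strata too small to screen).
#' @export
stratified_screen <- function(matrix, mg, strata, alpha = 0.05,
                              min_pairs = 10) {
  if (is.null(names(strata))) stopf("'strata' must be a named vector")
  labels <- sort(unique(strata))
  if (length(labels) != 2)
    stopf("exactly two strata are supported, got: %s",
          paste(labels, collapse = ", "))
  results <- list(); skipped <- character(0)
  for (lab in labels) {
    ids <- intersect(names(strata)[strata == lab],
                     intersect(colnames(matrix$values), names(mg)))
    if (length(ids) < min_pairs) {
      skipped <- c(skipped, lab)
      next
    }
    sub <- matrix
    sub$values <- matrix$values[, ids, drop = FALSE]
    sub$batch <- matrix$batch[ids]
    results[[lab]] <- spearman_screen(sub, mg, alpha = alpha,
                                      min_pairs = min_pairs, stratum = lab)
  }
  overlap <- NULL
  if (length(results) == 2) {
    overlap <- lapply(c(positive = "positive", negative = "negative"),
                      function(d) {
      s1 <- results[[1]]$feature[results[[1]]$significant &
                                   results[[1]]$direction == d]
      s2 <- results[[2]]$feature[results[[2]]$significant &
                                   results[[2]]$direction == d]
      out <- list(both = intersect(s1, s2),
                  only1 = setdiff(s1, s2), only2 = setdiff(s2, s1))
      names(out) <- c("both", paste0(names(results), "_only"))
      out$counts <- vapply(out[1:3], length, integer(1))
      out
    })
  }
  list(results = results, overlap = overlap, skipped = skipped)
}

#' Protein-adjusted phosphosite screen
#'
#' Tests whether phosphosite associations with Mg content hold independently
#' of the parent protein's abundance. Each site gets a marginal Spearman test
#' against Mg and a partial Spearman correlation controlling for the parent
#' protein (Pearson correlation of the rank-residuals, equivalently the
#' standard partial-correlation formula on rank correlations; p from the t
#' approximation on `n - 3` degrees of freedom). A site is flagged
#' protein-independent when marginal and partial tests are both significant
#' at `alpha` with concordant sign.
#'
#' @param phospho_matrix,protein_matrix [expression_matrix()] objects sharing
#'   sample ids.
#' @param mg named numeric Mg vector.
#' @param site_map named character vector site id -> parent protein id;
#'   by default parents are parsed from site ids of the form
#'   `<protein>_S<pos>`.
#' @param alpha significance level (default 0.05).
#' @param min_pairs minimum complete pairs (default 10).
#' @return data.frame with marginal and partial statistics per site, a
#'   `status` column (`ok`, `marginal_only` for unmapped parents,
#'   `partial_skipped` when the parent is missing in more than half of the
#'   site's complete pairs, `untested`), and `protein_independent`.
#' @export
protein_adjusted_phospho_screen <- function(phospho_matrix, protein_matrix,
                                            mg, site_map = NULL,
                                            alpha = 0.05, min_pairs = 10) {
  if (!inherits(phospho_matrix, "mg_expr") ||
      !inherits(protein_matrix, "mg_expr"))
    stopf("matrices must be mg_expr objects")
  sites <- rownames(phospho_matrix$values)
  if (is.null(site_map))
    site_map <- stats::setNames(sub("_S[0-9]+$", "", sites), sites)
  samples <- intersect(colnames(phospho_matrix$values), names(mg))
  pv <- phospho_matrix$values[, samples, drop = FALSE]
  prv <- protein_matrix$values[, intersect(colnames(protein_matrix$values),
                                           samples), drop = FALSE]
  mgv <- mg[samples]

  res <- lapply(sites, function(s) {
    sv <- pv[s, ]
    marg <- spearman_test(sv, mgv)
    row <- data.frame(site = s, parent = NA_character_,
                      rho_marginal = marg$rho, p_marginal = marg$p,
                      n = marg$n, rho_partial = NA_real_,
                      p_partial = NA_real_, n_partial = NA_integer_,
                      status = "ok", protein_independent = FALSE,
                      stringsAsFactors = FALSE)
    if (marg$n < min_pairs || is.na(marg$rho)) {
      row$status <- "untested"
      return(row)
    }
    parent <- unname(site_map[s])
    if (is.na(parent) || !parent %in% rownames(prv)) {
      row$status <- "marginal_only"
      return(row)
    }
    row$parent <- parent
    prot <- prv[parent, samples]
    pairs_ok <- is.finite(sv) & is.finite(mgv)
    triple_ok <- pairs_ok & is.finite(prot)
    if (sum(triple_ok) < sum(pairs_ok) / 2 || sum(triple_ok) < min_pairs) {
      row$status <- "partial_skipped"
      return(row)
    }
    rs <- rank(sv[triple_ok]); rm <- rank(mgv[triple_ok])
    rp <- rank(prot[triple_ok])
    nn <- sum(triple_ok)
    if (stats::sd(rp) == 0 || stats::sd(rs) == 0 || stats::sd(rm) == 0) {
      row$status <- "partial_skipped"
      return(row)
    }
    r_sm <- stats::cor(rs, rm); r_sp <- stats::cor(rs, rp)
    r_mp <- stats::cor(rm, rp)
    denom <- sqrt((1 - r_sp^2) * (1 - r_mp^2))
    rho_part <- if (denom < 1e-12) 0 else (r_sm - r_sp * r_mp) / denom
    rho_part <- max(min(rho_part, 1), -1)
    if (abs(rho_part) >= 1 - 1e-12) {
      p_part <- 2e-16
    } else {
      tt <- rho_part * sqrt((nn - 3) / (1 - rho_part^2))
      p_part <- 2 * stats::pt(-abs(tt), df = nn - 3)
    }
    row$rho_partial <- rho_part
    row$p_partial <- p_part
    row$n_partial <- nn
    row$protein_independent <- marg$p < alpha && p_part < alpha &&
      sign(marg$rho) == sign(rho_part)
    row
  })
  do.call(rbind, res)
}

#' Dichotomize patients into High-Mg and Low-Mg groups
#'
#' Splits a cohort on its Mg content by (default) the maximally selected
#' log-rank cutpoint against overall survival (see
#' [max_selected_cutpoint()]), by the median, or at a fixed threshold.
#' A sample is Low-Mg iff its Mg content is strictly below the threshold.
#' The returned threshold is reusable on a subcohort via [label_mg()].
#'
#' @param clinical data.frame with columns `sample`, `mg`, and (for the
#'   cutpoint method) `os_months`, `os_event`.
#' @param method `"max_logrank"`, `"median"` or `"fixed"`.
#' @param threshold required when `method = "fixed"`.
#' @param minprop minimum group proportion for the cutpoint scan.
#' @param n_perm permutations for the cutpoint p-value (0 to skip).
#' @param seed seed for the permutation p-value.
#' @return an `mg_groups` object: `threshold`, `labels` (named
#'   `"High-Mg"`/`"Low-Mg"` vector), `method`, `cutpoint` (the
#'   [max_selected_cutpoint()] result, when used).
#' @export
dichotomize_mg <- function(clinical,
                           method = c("max_logrank", "median", "fixed"),
                           threshold = NULL, minprop = 0.1, n_perm = 1000,
                           seed = NULL) {
  method <- match.arg(method)
  need <- c("sample", "mg")
  if (method == "max_logrank") need <- c(need, "os_months", "os_event")
  miss <- setdiff(need, names(clinical))
  if (length(miss)) stopf("clinical table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  if (anyNA(clinical$mg)) stopf("Mg content missing for some samples")
  cut_res <- NULL
  thr <- switch(method,
    median = stats::median(clinical$mg),
    fixed = {
      if (is.null(threshold)) stopf("method 'fixed' needs a threshold")
      threshold
    },
    max_logrank = {
      cut_res <- max_selected_cutpoint(clinical$os_months, clinical$os_event,
                                       clinical$mg, minprop = minprop,
                                       p_method = if (n_perm > 0)
                                         "permutation" else "none",
                                       n_perm = n_perm, seed = seed)
      cut_res$threshold
    })
  labels <- stats::setNames(
    ifelse(clinical$mg < thr, "Low-Mg", "High-Mg"), clinical$sample)
  structure(list(threshold = thr, labels = labels, method = method,
                 cutpoint = cut_res),
            class = "mg_groups")
}

#' @export
print.mg_groups <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("<mg_groups> threshold %.4g (%s): %s\n", x$threshold, x$method,
              paste(sprintf("%s n=%d", names(tab), as.integer(tab)),
                    collapse = ", ")))
  invisible(x)
}

#' Apply an existing Mg threshold to new samples
#'
#' @param groups an `mg_groups` from [dichotomize_mg()].
#' @param mg named numeric vector of Mg content.
#' @return named character vector of `"High-Mg"` / `"Low-Mg"` labels.
#' @export
label_mg <- function(groups, mg) {
  if (!inherits(groups, "mg_groups")) stopf("'groups' must be mg_groups")
  stats::setNames(ifelse(mg < groups$threshold, "Low-Mg", "High-Mg"),
                  names(mg))
}
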