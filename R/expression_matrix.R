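#' Expression matrix with processing-stage provenance
#'
#' A features x samples numeric matrix with `NA` encoding missing values,
#' a batch map, and a processing-stage tag. Stages advance strictly in the
#' order `raw -> scaled -> s_over_s -> log2 -> zscore`, mirroring the
#' cleaning pipeline (per-sample total-intensity scaling, division by the
#' internal-standard channel, log2 transform, dual z-scoring); operations
#' that receive a matrix at the wrong stage refuse to run.
#'
#' @param values numeric matrix, features in rows (rownames required),
#'   samples in columns (colnames required); `NA` marks missing.
#' @param stage processing stage tag, one of
#'   `"raw"`, `"scaled"`, `"s_over_s"`, `"log2"`, `"zscore"`.
#' @param batch named character vector mapping sample id to batch id, or
#'   `NULL` for a single unnamed batch.
#' @param note character vector of free-text provenance notes.
#' @return an object of class `mg_expr`.
#' @export
expression_matrix <- function(values, stage, batch = NULL, note = character()) {
  if (!is.matrix(values) || !is.numeric(values))
    stopf("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stopf("'values' must have feature rownames and sample colnames")
  stage <- match.arg(stage, expr_stages())
  if (is.null(batch)) {
    batch <- stats::setNames(rep("batch1", ncol(values)), colnames(values))
  }
  if (!all(colnames(values) %in% names(batch)))
    stopf("every sample must appear in the batch map")
  batch <- batch[colnames(values)]
  structure(
    list(values = values, stage = stage, batch = batch, note = note),
    class = "mg_expr"
  )
}

expr_stages <- function() c("raw", "scaled", "s_over_s", "log2", "zscore")

#' @export
print.mg_expr <- function(x, ...) {
  cat(sprintf(
    "<mg_expr> %d features x %d samples | stage: %s | %d batch(es) | %.1f%% missing\n",
    nrow(x$values), ncol(x$values), x$stage, length(unique(x$batch)),
    100 * mean(is.na(x$values))
  ))
  for (n in x$note) cat("  note:", n, "\n")
  invisible(x)
}

#' @export
dim.mg_expr <- function(x) dim(x$values)

require_stage <- function(mat, allowed, op) {
  if (!inherits(mat, "mg_expr"))
    stopf("%s() expects an 'mg_expr' expression matrix", op)
  if (!mat$stage %in% allowed)
    stopf("%s() requires stage %s, got '%s'", op,
          paste(sQuote(allowed), collapse = " or "), mat$stage)
  invisible(mat)
}

# advance the stage tag, enforcing the documented order
advance_stage <- function(mat, new_stage, note = NULL) {
  stages <- expr_stages()
  if (match(new_stage, stages) <= match(mat$stage, stages))
    stopf("stage may only advance forward (%s -> %s refused)",
          mat$stage, new_stage)
  mat$stage <- new_stage
  if (!is.null(note)) mat$note <- c(mat$note, note)
  mat
}
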