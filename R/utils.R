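# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  if (x < lower || x > upper)
    stopf("'%s' must be in [%s, %s], got %s", name, lower, upper, x)
  invisible(x)
}

assert_count <- function(x, name, min = 0L) {
  assert_scalar_number(x, name, lower = min)
  if (x != round(x)) stopf("'%s' must be an integer count", name)
  invisible(as.integer(x))
}

# Benjamini-Hochberg q-values; thin wrapper kept for one call point
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

# deterministic child seeds below 2^31, derived from a user seed
derive_seed <- function(seed, k) {
  (as.integer(seed) * 48271L + k * 1009L) %% 2147483587L
}
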