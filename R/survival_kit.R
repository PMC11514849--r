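# Self-contained survival statistics: Kaplan-Meier, log-rank, maximally
# selected log-rank cutpoint, Cox partial likelihood (Breslow ties).

check_surv <- function(time, event) {
  if (length(time) != length(event)) stopf("time/event length mismatch")
  if (!length(time)) stopf("no survival records")
  if (any(!is.finite(time)) || any(time <= 0))
    stopf("survival times must be finite and positive")
  if (!all(event %in% c(0, 1))) stopf("event must be 0 (censored) or 1")
  invisible(NULL)
}

#' Kaplan-Meier product-limit estimate
#'
#' Product-limit survival estimate over distinct event times with Greenwood
#' standard errors and log-log 95% confidence bands. At a tied event and
#' censoring time the event is processed first (the censored subject is
#' still at risk at that time).
#'
#' @param time positive survival times (months).
#' @param event 1 = deceased, 0 = censored.
#' @return a data.frame of class `mg_km`: `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv`, `se`, `lower`, `upper` (one row per distinct
#'   observed time).
#' @export
km_estimate <- function(time, event) {
  check_surv(time, event)
  o <- order(time)
  time <- time[o]; event <- event[o]
  ut <- unique(time)
  first <- !duplicated(time)
  n_risk <- (length(time):1)[first]
  d <- as.numeric(rowsum(event, time, reorder = TRUE))
  cns <- as.numeric(rowsum(1 - event, time, reorder = TRUE))
  surv <- cumprod(1 - d / n_risk)
  gw_terms <- ifelse(n_risk > d, d / (n_risk * (n_risk - d)), NA_real_)
  gw <- cumsum(ifelse(is.na(gw_terms), 0, gw_terms))
  se <- surv * sqrt(gw)
  z <- stats::qnorm(0.975)
  ok <- surv > 0 & surv < 1
  se_cll <- rep(NA_real_, length(surv))
  se_cll[ok] <- sqrt(gw[ok]) / abs(log(surv[ok]))
  lower <- upper <- rep(NA_real_, length(surv))
  lower[ok] <- surv[ok]^exp(z * se_cll[ok])
  upper[ok] <- surv[ok]^exp(-z * se_cll[ok])
  lower[surv == 1] <- 1; upper[surv == 1] <- 1
  lower[surv == 0] <- 0; upper[surv == 0] <- 0
  structure(
    data.frame(time = ut, n_risk = n_risk, n_event = d, n_censor = cns,
               surv = surv, se = se, lower = lower, upper = upper),
    class = c("mg_km", "data.frame")
  )
}

# per-distinct-time structures shared by every log-rank computation
lr_prep <- function(time, event) {
  o <- order(time)
  time <- time[o]; event <- event[o]
  first <- !duplicated(time)
  fidx <- cumsum(first)  # distinct-time index of each record
  list(o = o, time = time, event = event, fidx = fidx,
       n_risk = (length(time):1)[first],
       d = as.numeric(rowsum(event, fidx, reorder = TRUE)))
}

# standardized two-group log-rank statistic (O - E)/sqrt(V) for membership g
lr_z <- function(prep, g) {
  g <- as.numeric(g[prep$o])
  n1 <- rev(cumsum(rev(g)))[!duplicated(prep$fidx)]
  d1 <- as.numeric(rowsum(prep$event * g, prep$fidx, reorder = TRUE))
  n <- prep$n_risk; d <- prep$d
  oe <- sum(d1 - d * n1 / n)
  keep <- n > 1
  v <- sum((d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1))[keep])
  if (v <= 0) return(NA_real_)
  oe / sqrt(v)
}

#' Log-rank test for k groups
#'
#' Standard observed-minus-expected log-rank test over the pooled distinct
#' event times; chi-square statistic on k-1 degrees of freedom.
#'
#' @param time,event survival outcome (see [km_estimate()]).
#' @param group group label per record (2 or more distinct values).
#' @return list with `statistic`, `df`, `p`, `observed`, `expected`.
#' @export
logrank_test <- function(time, event, group) {
  check_surv(time, event)
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2) stopf("need at least 2 groups")
  group <- droplevels(group)
  k <- nlevels(group)
  prep <- lr_prep(time, event)
  g_sorted <- group[prep$o]
  first <- !duplicated(prep$fidx)
  n <- prep$n_risk; d <- prep$d
  G <- stats::model.matrix(~ g_sorted - 1)
  n_at <- apply(G, 2, function(col) rev(cumsum(rev(col)))[first])
  n_at <- matrix(n_at, ncol = k)
  d_g <- rowsum(prep$event * G, prep$fidx, reorder = TRUE)
  O <- colSums(d_g)
  E <- colSums(d * n_at / n)
  # covariance of (O - E), summed over distinct event times
  V <- matrix(0, k, k)
  keep <- which(d > 0 & n > 1)
  for (t in keep) {
    pi_t <- n_at[t, ] / n[t]
    c_t <- d[t] * (n[t] - d[t]) / (n[t] - 1)
    V <- V + c_t * (diag(pi_t, k) - tcrossprod(pi_t))
  }
  idx <- seq_len(k - 1)
  oe <- (O - E)[idx]
  Vi <- V[idx, idx, drop = FALSE]
  stat <- if (all(abs(oe) < 1e-12)) 0 else
    as.numeric(crossprod(oe, solve(Vi, oe)))
  p <- stats::pchisq(stat, df = k - 1, lower.tail = FALSE)
  list(statistic = stat, df = k - 1L, p = p,
       observed = stats::setNames(O, levels(group)),
       expected = stats::setNames(E, levels(group)))
}

#' Maximally selected log-rank cutpoint
#'
#' Scans every admissible dichotomization of a continuous covariate
#' (midpoints between sorted distinct values leaving at least
#' `ceil(minprop * n)` samples on each side), computes the standardized
#' two-group log-rank statistic at each, and returns the threshold with the
#' largest absolute statistic. The p-value of the maximally selected
#' statistic is computed by permuting the covariate against the (time,
#' event) pairs and recording the permutation distribution of the maximum;
#' the naive p-value treating the selected split as a single pre-specified
#' test is also reported (it is anti-conservative).
#'
#' @param time,event survival outcome.
#' @param covariate continuous covariate to dichotomize.
#' @param minprop minimum proportion of samples per side (default 0.1).
#' @param p_method `"permutation"` or `"none"`.
#' @param n_perm number of permutations (default 2000).
#' @param seed optional seed for the permutation draw.
#' @return an `mg_cutpoint` list: `threshold`, `max_stat` (standardized
#'   log-rank statistic at the threshold), `p` (permutation), `p_naive`,
#'   `n_low`, `n_high`, `scan` (threshold/statistic table), `n_perm`.
#' @export
max_selected_cutpoint <- function(time, event, covariate, minprop = 0.1,
                                  p_method = c("permutation", "none"),
                                  n_perm = 2000, seed = NULL) {
  p_method <- match.arg(p_method)
  check_surv(time, event)
  if (length(covariate) != length(time)) stopf("covariate length mismatch")
  if (sum(event) == 0) stopf("no events: cutpoint search is degenerate")
  n <- length(covariate)
  vals <- sort(unique(covariate))
  if (length(vals) < 2) stopf("need at least 2 distinct covariate values")
  mids <- (vals[-1] + vals[-length(vals)]) / 2
  min_n <- ceiling(minprop * n)
  n_low_all <- vapply(mids, function(m) sum(covariate < m), integer(1))
  admissible <- n_low_all >= min_n & (n - n_low_all) >= min_n
  if (!any(admissible)) stopf("no admissible threshold respects minprop")
  mids <- mids[admissible]
  prep <- lr_prep(time, event)

  scan_max <- function(cov) {
    z <- vapply(mids, function(m) lr_z(prep, cov < m), numeric(1))
    z
  }
  z_obs <- scan_max(covariate)
  if (all(is.na(z_obs))) stopf("log-rank variance degenerate at every split")
  best <- which.max(abs(z_obs))
  max_stat <- z_obs[best]
  p_naive <- 2 * stats::pnorm(-abs(max_stat))
  p <- NA_real_
  if (p_method == "permutation") {
    if (!is.null(seed)) set.seed(seed)
    perm_max <- vapply(seq_len(n_perm), function(i) {
      z <- scan_max(sample(covariate))
      max(abs(z), na.rm = TRUE)
    }, numeric(1))
    p <- (1 + sum(perm_max >= abs(max_stat) - 1e-12)) / (n_perm + 1)
  }
  structure(
    list(threshold = mids[best], max_stat = max_stat, p = p,
         p_naive = p_naive,
         n_low = sum(covariate < mids[best]),
         n_high = sum(covariate >= mids[best]),
         scan = data.frame(threshold = mids, stat = z_obs),
         n_perm = if (p_method == "permutation") n_perm else 0L),
    class = "mg_cutpoint"
  )
}

#' @export
print.mg_cutpoint <- function(x, ...) {
  cat(sprintf(
    "<mg_cutpoint> threshold %.4g | |z| = %.3f | n = %d/%d | perm p = %s\n",
    x$threshold, abs(x$max_stat), x$n_low, x$n_high,
    ifelse(is.na(x$p), "not computed", format(x$p, digits = 3))))
  invisible(x)
}

#' Cox proportional-hazards fit by partial likelihood
#'
#' Newton-Raphson maximization of the Breslow partial likelihood with
#' step-halving; convergence when the largest score component drops below
#' `1e-8` or the relative log-likelihood change below `1e-10`. Wald
#' standard errors come from the observed information. A monotone likelihood
#' (perfect separation) is flagged as non-converged.
#'
#' @param time,event survival outcome.
#' @param covariates numeric vector or matrix (samples x covariates).
#' @param max_iter Newton-Raphson iteration cap.
#' @return an `mg_cox` list: `coef`, `se`, `hr`, `ci_lower`, `ci_upper`,
#'   `loglik` (null and fitted), `score_z`, `converged`, `iterations`,
#'   `diagnostic`.
#' @export
cox_fit <- function(time, event, covariates, max_iter = 50) {
  check_surv(time, event)
  x <- as.matrix(covariates)
  if (nrow(x) != length(time)) stopf("covariate rows must match records")
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  const <- apply(x, 2, function(col) stats::sd(col) == 0)
  if (any(const)) stopf("constant covariate(s): %s",
                        paste(colnames(x)[const], collapse = ", "))
  if (sum(event) < ncol(x))
    stopf("fewer events (%d) than covariates (%d)", sum(event), ncol(x))
  p <- ncol(x)

  o <- order(-time)  # descending: risk sets grow by cumulation
  xt <- x[o, , drop = FALSE]
  tt <- time[o]; ee <- event[o]
  # risk set at an event time t = all records with time >= t; with the
  # descending sort that is the cumulative prefix through the tie block
  block_last <- cumsum(rle(tt)$lengths)       # last index of each tie block
  # tie-block id of each row: smallest j with block_last[j] >= i
  blk <- findInterval(seq_along(tt) - 1L, block_last) + 1L
  last_of_blk <- block_last[blk]
  ev_rows <- which(ee == 1)

  partial <- function(beta) {
    eta <- as.numeric(xt %*% beta)
    w <- exp(eta)
    cw <- cumsum(w)
    cwx <- apply(xt * w, 2, cumsum)
    cwx <- matrix(cwx, ncol = p)
    # S2 cumulations for the information matrix
    cwxx <- array(0, c(length(tt), p, p))
    for (a in seq_len(p)) for (b in seq_len(a)) {
      s <- cumsum(xt[, a] * xt[, b] * w)
      cwxx[, a, b] <- s; cwxx[, b, a] <- s
    }
    ll <- 0; score <- numeric(p); info <- matrix(0, p, p)
    for (i in ev_rows) {
      li <- last_of_blk[i]
      s0 <- cw[li]
      s1 <- cwx[li, ]
      s2 <- matrix(cwxx[li, , ], p, p)
      ll <- ll + eta[i] - log(s0)
      score <- score + xt[i, ] - s1 / s0
      info <- info + s2 / s0 - tcrossprod(s1 / s0)
    }
    list(ll = ll, score = score, info = info)
  }

  beta <- numeric(p)
  pl0 <- partial(beta)
  ll_null <- pl0$ll
  score_z <- tryCatch(
    as.numeric(pl0$score / sqrt(diag(pl0$info))), error = function(e) NA)
  ll_old <- pl0$ll
  converged <- FALSE; diagnostic <- NA_character_
  pl <- pl0
  for (it in seq_len(max_iter)) {
    step <- tryCatch(solve(pl$info, pl$score), error = function(e) NULL)
    if (is.null(step)) { diagnostic <- "singular information"; break }
    halve <- 0
    repeat {
      beta_new <- beta + step / 2^halve
      pl_new <- partial(beta_new)
      if (is.finite(pl_new$ll) && pl_new$ll >= pl$ll - 1e-12) break
      halve <- halve + 1
      if (halve > 20) break
    }
    if (halve > 20) { diagnostic <- "step-halving failed"; break }
    rel <- abs(pl_new$ll - ll_old) / (abs(ll_old) + 1e-10)
    beta <- beta_new; pl <- pl_new
    if (max(abs(pl$score)) < 1e-8 || rel < 1e-10) { converged <- TRUE; break }
    ll_old <- pl$ll
  }
  if (converged && any(abs(beta) > 15)) {
    converged <- FALSE
    diagnostic <- "monotone likelihood (perfect separation?)"
  }
  se <- tryCatch(sqrt(diag(solve(pl$info))), error = function(e)
    rep(NA_real_, p))
  z <- stats::qnorm(0.975)
  structure(
    list(coef = stats::setNames(beta, colnames(x)),
         se = stats::setNames(se, colnames(x)),
         hr = exp(beta), ci_lower = exp(beta - z * se),
         ci_upper = exp(beta + z * se),
         loglik = c(null = ll_null, fitted = pl$ll),
         score_z = score_z,
         converged = converged, iterations = it,
         diagnostic = diagnostic),
    class = "mg_cox"
  )
}

#' @export
print.mg_cox <- function(x, ...) {
  cat("<mg_cox>", if (x$converged) "converged" else
    paste("NOT converged:", x$diagnostic), "\n")
  print(data.frame(coef = x$coef, se = x$se, hr = x$hr,
                   lower95 = x$ci_lower, upper95 = x$ci_upper))
  invisible(x)
}
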