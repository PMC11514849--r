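test_that("spearman test recovers perfect monotone association", {
  mg <- c(a = 200, b = 340, c = 500, d = 660, e = 820, f = 900,
          g = 250, h = 410, i = 570, j = 730, k = 880, l = 300)
  v <- rbind(same = mg, flipped = -mg, const = rep(1, 12))
  m <- expression_matrix(v, "log2")
  sc <- spearman_screen(m, mg, min_pairs = 10)
  expect_equal(sc$rho[sc$feature == "same"], 1)
  expect_equal(sc$rho[sc$feature == "flipped"], -1)
  expect_equal(sc$direction[sc$feature == "same"], "positive")
  expect_equal(sc$direction[sc$feature == "flipped"], "negative")
  expect_false(sc$tested[sc$feature == "const"])
  expect_match(sc$reason[sc$feature == "const"], "constant")
})

test_that("small-sample spearman p equals the full permutation enumeration", {
  # ties in both vectors: enumeration must use average ranks
  x <- c(3, 1, 4, 1, 5, 9)
  y <- c(2, 7, 1, 8, 2, 8)
  ts <- spearman_test(x, y)
  expect_equal(ts$method, "exact_permutation")
  expect_equal(ts$p, spearman_oracle(x, y), tolerance = 1e-12)
  set.seed(11)
  for (rep in 1:5) {
    x <- sample(1:8, 6, replace = TRUE)
    y <- rnorm(6)
    expect_equal(spearman_test(x, y)$p, spearman_oracle(x, y),
                 tolerance = 1e-12)
  }
  # large-n branch agrees with the standard t approximation
  set.seed(12)
  x <- rnorm(40); y <- 0.5 * x + rnorm(40)
  ts2 <- spearman_test(x, y)
  ref <- cor.test(x, y, method = "spearman", exact = FALSE)
  expect_equal(ts2$rho, unname(ref$estimate))
  expect_equal(ts2$p, ref$p.value, tolerance = 1e-10)
})

test_that("the screen is invariant under monotone transforms of Mg", {
  set.seed(21)
  v <- matrix(rnorm(15 * 30), 15, 30,
              dimnames = list(sprintf("F%02d", 1:15), sprintf("s%02d", 1:30)))
  m <- expression_matrix(v, "log2")
  mg <- setNames(runif(30, 162, 920), colnames(v))
  s1 <- spearman_screen(m, mg)
  s2 <- spearman_screen(m, log(mg))
  s3 <- spearman_screen(m, rank(mg))
  expect_equal(s1$rho, s2$rho)
  expect_equal(s1$p, s2$p)
  expect_equal(s1$rho, s3$rho)
  expect_equal(s1$p, s3$p)
})

test_that("stratified screen set algebra is exact", {
  set.seed(22)
  n <- 48
  samples <- sprintf("s%02d", 1:n)
  mg <- setNames(runif(n, 162, 920), samples)
  strata <- setNames(rep(c("left", "right"), each = n / 2), samples)
  # one feature correlated only in the right stratum, one in both
  right <- strata == "right"
  v <- rbind(
    right_only = ifelse(right, mg + rnorm(n, 0, 60), rnorm(n, 500, 200)),
    both = mg + rnorm(n, 0, 60),
    null1 = rnorm(n), null2 = rnorm(n))
  colnames(v) <- samples
  m <- expression_matrix(v, "log2")
  out <- stratified_screen(m, mg, strata, min_pairs = 10)
  expect_setequal(names(out$results), c("left", "right"))
  ov <- out$overlap$positive
  expect_true("right_only" %in% ov$right_only)
  expect_true("both" %in% ov$both)
  # |both| + |left-only| = |left significant| per direction
  left_sig <- out$results$left
  expect_equal(length(ov$both) + length(ov$left_only),
               sum(left_sig$significant & left_sig$direction == "positive"))

  # identical data in both strata: overlap is the full significant set
  v2 <- cbind(v[, 1:24], v[, 1:24])
  colnames(v2) <- samples
  mg2 <- setNames(rep(mg[1:24], 2), samples)
  out2 <- stratified_screen(expression_matrix(v2, "log2"), mg2, strata)
  for (d in c("positive", "negative")) {
    expect_length(out2$overlap[[d]]$left_only, 0)
    expect_length(out2$overlap[[d]]$right_only, 0)
  }
  # a stratum below min_pairs is skipped and reported
  strata3 <- setNames(c(rep("left", 5), rep("right", n - 5)), samples)
  out3 <- stratified_screen(m, mg, strata3, min_pairs = 10)
  expect_equal(out3$skipped, "left")
  expect_null(out3$overlap)
})

test_that("protein-adjusted screen separates protein-driven from independent sites", {
  set.seed(23)
  n <- 100
  samples <- sprintf("s%03d", 1:n)
  mg <- setNames(runif(n, 162, 920), samples)
  z <- scale(rank(mg))[, 1]
  prot_driven <- 0.7 * z + 0.7 * rnorm(n)   # protein correlated with Mg
  prot_null <- rnorm(n)                      # protein independent of Mg
  pv <- rbind(
    # site tracks its Mg-correlated parent: marginal yes, partial no
    PDRV_S10 = prot_driven + 0.3 * rnorm(n),
    # site independently correlated, parent null: partial ~ marginal
    PNUL_S20 = 0.6 * z + 0.8 * rnorm(n),
    # site with unmapped parent
    NOPE_S30 = rnorm(n))
  colnames(pv) <- samples
  prm <- rbind(PDRV = prot_driven, PNUL = prot_null)
  colnames(prm) <- samples
  res <- protein_adjusted_phospho_screen(
    expression_matrix(pv, "zscore"), expression_matrix(prm, "zscore"), mg)
  r <- function(s, col) res[res$site == s, col]
  expect_equal(r("NOPE_S30", "status"), "marginal_only")
  expect_true(r("PDRV_S10", "p_marginal") < 0.05)
  expect_false(r("PDRV_S10", "protein_independent"))
  expect_true(r("PNUL_S20", "protein_independent"))
  expect_equal(r("PNUL_S20", "rho_partial"), r("PNUL_S20", "rho_marginal"),
               tolerance = 0.12)

  # site exactly equal to its parent: partial correlation collapses
  pv2 <- rbind(PDRV_S99 = prot_driven)
  colnames(pv2) <- samples
  res2 <- protein_adjusted_phospho_screen(
    expression_matrix(pv2, "zscore"), expression_matrix(prm, "zscore"), mg)
  expect_false(res2$protein_independent)
})

test_that("partial screen calibration and power behave as designed", {
  # protein drives the Mg association; sites add independent noise:
  # partial detections should stay near the nominal error rate, while
  # independently planted sites at |rho| ~ 0.5 are detected with power > 0.8
  set.seed(24)
  n <- 100; n_rep <- 150
  hits_null <- hits_planted <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    mg <- runif(n, 162, 920)
    names(mg) <- sprintf("s%03d", 1:n)
    z <- scale(rank(mg))[, 1]
    prot <- 0.75 * z + 0.6 * rnorm(n)
    site_null <- prot + 0.5 * rnorm(n)          # fully protein-driven
    site_planted <- 0.58 * z + 0.8 * rnorm(n)   # independent, rho ~ 0.5
    pv <- rbind(P1_S1 = site_null, P2_S2 = site_planted)
    colnames(pv) <- names(mg)
    prm <- rbind(P1 = prot, P2 = rnorm(n))
    colnames(prm) <- names(mg)
    res <- protein_adjusted_phospho_screen(
      expression_matrix(pv, "zscore"), expression_matrix(prm, "zscore"), mg)
    hits_null[i] <- res$protein_independent[res$site == "P1_S1"]
    hits_planted[i] <- res$protein_independent[res$site == "P2_S2"]
  }
  expect_lte(mean(hits_null), 0.10)
  expect_gt(mean(hits_planted), 0.8)
})

test_that("Mg dichotomization supports median, fixed and cutpoint modes", {
  cl <- data.frame(sample = sprintf("s%d", 1:4), mg = c(1, 2, 3, 4))
  g <- dichotomize_mg(cl, method = "median")
  expect_equal(g$threshold, 2.5)
  expect_equal(as.integer(table(g$labels)[c("High-Mg", "Low-Mg")]),
               c(2L, 2L))
  g2 <- dichotomize_mg(cl, method = "fixed", threshold = 3.5)
  expect_equal(sum(g2$labels == "Low-Mg"), 3)
  # Low-Mg iff mg < threshold, reusable on new samples
  expect_equal(unname(label_mg(g2, c(x = 3.4, y = 3.5))),
               c("Low-Mg", "High-Mg"))

  # cutpoint mode lands in the gap between two hazard-separated Mg clusters
  set.seed(25)
  n <- 90
  mg <- c(sample(c(200, 280, 360), n / 2, replace = TRUE),
          sample(c(620, 700, 780), n / 2, replace = TRUE))
  tt <- ceiling(rexp(n, ifelse(mg < 475, 0.08, 0.015)))
  cl3 <- data.frame(sample = sprintf("s%02d", 1:n), mg = mg,
                    os_months = tt, os_event = rbinom(n, 1, 0.9))
  g3 <- dichotomize_mg(cl3, method = "max_logrank", n_perm = 200, seed = 5)
  expect_gt(g3$threshold, 360)
  expect_lt(g3$threshold, 620)
  expect_lt(g3$cutpoint$p, 0.05)

  # degenerate survival: no events
  cl4 <- data.frame(sample = sprintf("s%d", 1:20), mg = runif(20),
                    os_months = rep(10, 20), os_event = 0)
  expect_error(dichotomize_mg(cl4, method = "max_logrank"), "no events")
})
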