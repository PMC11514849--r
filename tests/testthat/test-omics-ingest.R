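test_that("quant table reading enforces the dialect", {
  tab <- make_quant(matrix(1:20, 10, 2))
  tab$meta$Contaminant[c(2, 5)] <- "+"
  p <- write_quant_tsv(tab, tempfile(fileext = ".tsv"))
  rt <- read_quant_table(p, "protein")
  expect_equal(nrow(rt$intensities), 8)        # flagged rows removed
  expect_false(any(c("F02", "F05") %in% rownames(rt$intensities)))

  # missing IS channel
  rt2 <- expect_error(read_quant_table(p, "protein", is_channel = "POOL"),
                      "internal-standard channel")
  # missing metadata column
  df <- read.delim(p)
  df$Unique_Peptides <- NULL
  p2 <- tempfile(fileext = ".tsv")
  write.table(df, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_quant_table(p2, "protein"), "Unique_Peptides")
  # malformed numeric names row and column
  df <- read.delim(p)
  df$Intensity_S01[3] <- "oops"
  write.table(df, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_quant_table(p2, "protein"), "Intensity_S01")
  # unknown columns warn and are dropped
  df <- read.delim(p)
  df$Gene_Names <- "x"
  write.table(df, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(read_quant_table(p2, "protein"), "Gene_Names")
})

test_that("identification-quality filters use the documented strict bounds", {
  tab <- make_quant(matrix(1, 4, 2), unique_peptides = c(1L, 2L, 3L, 1L))
  f <- filter_features(tab)
  expect_equal(rownames(f$intensities), c("F02", "F03"))

  ph <- make_quant(matrix(1, 4, 2), kind = "phospho",
                   loc_prob = c(0.74, 0.75, 0.7501, 0.9))
  fp <- filter_features(ph)
  # exactly 0.75 is dropped: the cutoff is strictly greater-than
  expect_equal(rownames(fp$intensities), c("F03", "F04"))

  all_pass <- filter_features(make_quant(matrix(1, 3, 2)))
  expect_equal(nrow(all_pass$intensities), 3)
})

test_that("total-intensity scaling equalizes channel sums, zeros preserved", {
  tab <- make_quant(cbind(c(60, 40, 0), c(100, 60, 40)), is = c(50, 40, 30))
  sc <- scale_total_intensity(tab)
  sums <- colSums(sc$intensities)
  expect_equal(unname(sums), rep(mean(c(120, 100, 200)), 3))
  expect_equal(sc$intensities[3, "S01"], 0)   # zero stays zero

  # random table: column sums equal within 1e-9 relative
  set.seed(1)
  tab2 <- make_quant(matrix(rexp(60, 1e-6), 10, 6))
  s2 <- colSums(scale_total_intensity(tab2)$intensities)
  expect_lt(diff(range(s2)) / mean(s2), 1e-9)

  tab3 <- make_quant(cbind(c(0, 0), c(1, 2)), is = c(1, 1))
  expect_error(scale_total_intensity(tab3), "all-zero")
})

test_that("IS bridging forms S/S values and propagates missingness", {
  v <- cbind(A = c(2, 4, 6), B = c(1, 8, 0))
  tab <- make_quant(v, is = c(2, 4, 6))
  em <- bridge_to_is(scale_total_intensity(make_quant(v, is = v[, "A"])))
  expect_equal(unname(em$values[, "A"]), c(1, 1, 1))  # self-ratio
  expect_equal(em$stage, "s_over_s")
  expect_false("IS" %in% colnames(em$values))

  # zero IS wipes the row; zero sample value becomes missing
  tab2 <- make_quant(cbind(A = c(2, 3), B = c(4, 5)), is = c(0, 1))
  tab2$stage <- "scaled"
  em2 <- bridge_to_is(tab2)
  expect_true(all(is.na(em2$values[1, ])))
  expect_false(anyNA(em2$values[2, ]))

  # stage contract
  expect_error(bridge_to_is(make_quant(v)), "stage 'scaled'")
})

test_that("multiplying a whole batch by a constant leaves S/S unchanged", {
  set.seed(4)
  v <- matrix(rexp(40, 1e-6), 8, 5)
  t1 <- make_quant(v)
  t2 <- make_quant(v * 37.5)
  t2$intensities <- t1$intensities * 37.5
  e1 <- bridge_to_is(scale_total_intensity(t1))
  e2 <- bridge_to_is(scale_total_intensity(t2))
  expect_equal(e1$values, e2$values, tolerance = 1e-12)
})

test_that("batch combination outer-joins features and rejects duplicates", {
  m1 <- expression_matrix(matrix(1:4, 2, 2, dimnames = list(c("F1", "F2"),
                                                            c("s1", "s2"))),
                          "s_over_s", setNames(c("b1", "b1"), c("s1", "s2")))
  m2 <- expression_matrix(matrix(5:8, 2, 2, dimnames = list(c("F1", "F3"),
                                                            c("s3", "s4"))),
                          "s_over_s", setNames(c("b2", "b2"), c("s3", "s4")))
  cm <- combine_batches(list(m1, m2))
  expect_equal(dim(cm$values), c(3L, 4L))
  expect_equal(cm$stage, "log2")
  expect_true(all(is.na(cm$values["F2", c("s3", "s4")])))
  expect_equal(cm$values["F1", "s1"], log2(1))
  m_dup <- m2; colnames(m_dup$values) <- c("s1", "s4")
  m_dup$batch <- setNames(c("b2", "b2"), c("s1", "s4"))
  expect_error(combine_batches(list(m1, m_dup)), "duplicate sample")

  b <- small_cohort()
  d <- tempfile(); write_cohort(b, d)
  mats <- lapply(names(b$batches), function(bb)
    bridge_to_is(scale_total_intensity(read_quant_table(
      file.path(d, sprintf("%s_proteins.tsv", bb)), "protein"))))
  big <- combine_batches(mats)
  expect_equal(ncol(big$values), 80)  # 40 patients x 2 tissues
})

test_that("z-scoring standardizes observed entries and flags degenerates", {
  m <- expression_matrix(
    matrix(c(1, 2, 3, 5, 5, 5), 2, 3, byrow = TRUE,
           dimnames = list(c("F1", "F2"), c("s1", "s2", "s3"))),
    "log2")
  zr <- zscore(m, axes = "rows")
  expect_equal(unname(zr$values["F1", ]), c(-1, 0, 1))
  expect_true(all(is.na(zr$values["F2", ])))  # constant row wiped

  set.seed(2)
  big <- expression_matrix(
    matrix(rnorm(600), 20, 30,
           dimnames = list(sprintf("F%02d", 1:20), sprintf("s%02d", 1:30))),
    "log2")
  big$values[sample(600, 60)] <- NA
  z <- zscore(big)
  rm_ <- apply(z$values, 1, mean, na.rm = TRUE)
  rs_ <- apply(z$values, 1, sd, na.rm = TRUE)
  expect_true(all(abs(rm_) < 1e-9))
  expect_true(all(abs(rs_ - 1) < 1e-9))

  # stage discipline: z-scoring twice or from the wrong stage is refused
  expect_error(zscore(z), "requires stage")
  expect_error(zscore(expression_matrix(big$values, "raw")),
               "requires stage")
})

test_that("missingness filter is a strict bound and idempotent", {
  v <- matrix(1, 3, 100,
              dimnames = list(c("half", "over", "full"),
                              sprintf("s%03d", 1:100)))
  v["half", 1:50] <- NA    # exactly 50%: retained
  v["over", 1:51] <- NA    # 51%: removed
  m <- expression_matrix(v, "log2")
  f <- filter_missing(m)
  expect_equal(rownames(f$values), c("half", "full"))
  f2 <- filter_missing(f)
  expect_equal(f$values, f2$values)
  # all-observed matrix passes unchanged
  m2 <- expression_matrix(matrix(1:4, 2, 2, dimnames = list(c("a", "b"),
                                                            c("x", "y"))),
                          "log2")
  expect_equal(filter_missing(m2)$values, m2$values)
})

test_that("differential abundance matches exact rank-sum behavior", {
  v <- rbind(F1 = c(1, 2, 3, 4, 5, 6))
  colnames(v) <- sprintf("s%d", 1:6)
  m <- expression_matrix(v, "log2")
  # fully separated groups: exact p = 2 * 1/choose(6,3) = 0.1
  r <- differential_abundance(m, c("s1", "s2", "s3"), c("s4", "s5", "s6"))
  expect_equal(r$p, 2 / choose(6, 3))
  expect_equal(r$effect, median(c(1, 2, 3)) - median(c(4, 5, 6)))
  # identical groups: effect 0, p at the null center
  v2 <- rbind(F1 = rep(c(5, 7, 9), 2))
  colnames(v2) <- sprintf("s%d", 1:6)
  m2 <- expression_matrix(v2, "log2")
  r2 <- differential_abundance(m2, c("s1", "s2", "s3"), c("s4", "s5", "s6"))
  expect_equal(r2$effect, 0)
  expect_gt(r2$p, 0.9)
  # paired effect: median of within-pair differences
  r3 <- differential_abundance(m, c("s1", "s2", "s3"), c("s4", "s5", "s6"),
                               paired = TRUE)
  expect_equal(r3$effect, -3)
  expect_error(differential_abundance(m, character(0), "s1"), "empty group")

  # exhaustive-permutation oracle for several small configurations
  set.seed(9)
  for (na in c(3, 5)) for (nb in c(4, 7)) {
    x <- rnorm(na, 0, 2); y <- rnorm(nb, 1, 2)
    vv <- rbind(F1 = c(x, y))
    colnames(vv) <- sprintf("s%d", seq_along(vv[1, ]))
    mm <- expression_matrix(vv, "log2")
    ra <- differential_abundance(mm, colnames(vv)[seq_len(na)],
                                 colnames(vv)[na + seq_len(nb)])
    expect_equal(ra$p, wilcox_oracle(x, y), tolerance = 1e-10,
                 label = sprintf("n=(%d,%d)", na, nb))
  }
})

test_that("cell-experiment flag applies the ratio and p cutoffs jointly", {
  ratio <- c(1.5, 1.19, 0.80, 0.84, 2.0)
  p <- c(0.01, 0.01, 0.04, 0.01, 0.2)
  expect_equal(flag_cell_differential(ratio, p),
               c(TRUE, FALSE, TRUE, FALSE, FALSE))
})
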