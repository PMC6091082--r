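test_that("median-of-ratios size factors match the hand-computed oracle", {
  m <- matrix(c(10, 20, 20, 40, 30, 60), nrow = 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("L1", "L2")))
  sf <- compute_size_factors(m)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-10)
  # identical libraries: all factors one
  m2 <- cbind(L1 = c(5, 50, 500), L2 = c(5, 50, 500))
  expect_equal(unname(compute_size_factors(m2)), c(1, 1))
  # scale equivariance: tripling one library triples its factor relative
  # to the others (factors are defined up to the geometric-mean gauge)
  m3 <- m; m3[, 2] <- m3[, 2] * 3
  sf3 <- compute_size_factors(m3)
  expect_equal((sf3[["L2"]] / sf3[["L1"]]) / (sf[["L2"]] / sf[["L1"]]), 3,
               tolerance = 1e-10)
})

test_that("size factors demand at least one zero-free row", {
  m <- matrix(c(0, 5, 5, 0), nrow = 2)
  colnames(m) <- c("L1", "L2")
  expect_error(compute_size_factors(m), "pseudocount")
})

test_that("identical conditions give a null result", {
  m <- matrix(rep(c(100, 200, 400), each = 8), nrow = 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"),
                              c("CT_1", "CT_2", "DK_1", "DK_2",
                                "HL_1", "HL_2", "HT_1", "HT_2")))
  res <- nb_contrast_test(m, setNames(rep(1, 8), colnames(m)), c("DK", "CT"))
  expect_equal(res$log2fc, rep(0, 3))
  expect_equal(res$p_value, rep(1, 3), tolerance = 1e-6)
})

test_that("swapping treatment and control negates the fold change", {
  m <- null_count_matrix(17, n = 50)
  sf <- compute_size_factors(m)
  fwd <- nb_contrast_test(m, sf, c("DK", "CT"))
  bwd <- nb_contrast_test(m, sf, c("CT", "DK"))
  expect_equal(fwd$log2fc, -bwd$log2fc)
  expect_equal(fwd$p_value, bwd$p_value, tolerance = 1e-12)
})

test_that("a single replicate is refused", {
  m <- null_count_matrix(1, n = 10)[, c("CT_1", "DK_1", "DK_2")]
  expect_error(nb_contrast_test(m, setNames(rep(1, 3), colnames(m)),
                                c("DK", "CT")), "replicates")
})

test_that("BH adjustment matches the hand computation and its invariants", {
  res <- data.frame(tss_id = letters[1:4], contrast = "DK/CT",
                    base_mean = 100, log2fc = c(2, -2, 0.5, 3),
                    p_value = c(0.01, 0.02, 0.03, 0.04))
  out <- call_det(res)
  expect_equal(out$padj, rep(0.04, 4))
  expect_true(all(out$padj >= out$p_value))
  # BH monotone in p rank, bounded by one
  res2 <- data.frame(tss_id = letters[1:6], contrast = "DK/CT",
                     base_mean = 1, log2fc = 0,
                     p_value = c(0.001, 0.5, 0.9, 0.04, 0.2, 1))
  out2 <- call_det(res2)
  o <- order(out2$p_value)
  expect_true(all(diff(out2$padj[o]) >= -1e-12))
  expect_true(all(out2$padj <= 1))
})

test_that("the DET rule is a sharp double threshold", {
  res <- data.frame(tss_id = c("a", "b", "c", "d"), contrast = "HL/CT",
                    base_mean = 100,
                    log2fc = c(0.99, -1.2, 1.5, 1.0),
                    p_value = c(1e-6, 1e-4, 0.5, 1e-6))
  out <- call_det(res)
  expect_false(out$is_det[out$tss_id == "a"])  # |lfc| just below 1
  expect_true(out$is_det[out$tss_id == "b"])
  expect_false(out$is_det[out$tss_id == "c"])  # padj too large
  expect_true(out$is_det[out$tss_id == "d"])   # lfc exactly 1 counts
})

test_that("null counts give calibrated p values and BH-controlled DETs", {
  fracs <- vapply(1:5, function(seed) {
    m <- null_count_matrix(seed)
    sf <- compute_size_factors(m)
    res <- nb_contrast_test(m, sf, c("DK", "CT"))
    det <- call_det(res)
    expect_lte(sum(det$is_det), 5)  # <= q * m false discoveries expected
    mean(res$p_value <= 0.05)
  }, 0)
  ci_half <- 1.96 * sqrt(0.05 * 0.95 / 500)
  expect_true(all(abs(fracs - 0.05) <= ci_half))
  # the average over seeds should sit near the nominal level
  expect_lt(abs(mean(fracs) - 0.05), ci_half)
})

test_that("planted two-fold-change TSSs are recovered as DETs", {
  set.seed(23)
  n_eff <- 100; n_null <- 400
  lfc <- c(sample(c(-2, 2), n_eff, replace = TRUE), rep(0, n_null))
  mu_ct <- 500
  mu_dk <- mu_ct * 2^lfc
  m <- cbind(
    CT_1 = rnbinom(500, mu = mu_ct, size = 20),
    CT_2 = rnbinom(500, mu = mu_ct, size = 20),
    DK_1 = rnbinom(500, mu = mu_dk, size = 20),
    DK_2 = rnbinom(500, mu = mu_dk, size = 20),
    HL_1 = rnbinom(500, mu = mu_ct, size = 20),
    HL_2 = rnbinom(500, mu = mu_ct, size = 20),
    HT_1 = rnbinom(500, mu = mu_ct, size = 20),
    HT_2 = rnbinom(500, mu = mu_ct, size = 20))
  rownames(m) <- sprintf("t%04d", 1:500)
  sf <- compute_size_factors(m)
  det <- call_det(nb_contrast_test(m, sf, c("DK", "CT")))
  recall <- mean(det$is_det[seq_len(n_eff)])
  expect_gte(recall, 0.90)
  # estimates concentrate near the planted magnitude
  expect_lt(median(abs(abs(det$log2fc[seq_len(n_eff)]) - 2)), 0.4)
})

test_that("fold-change estimates track an independent NB GLM fit", {
  m <- null_count_matrix(31, n = 60, mu = 300)
  m[1:10, c("DK_1", "DK_2")] <- m[1:10, c("DK_1", "DK_2")] * 4L
  sf <- compute_size_factors(m)
  mine <- nb_contrast_test(m, sf, c("DK", "CT"))
  dds <- DESeq2::DESeqDataSetFromMatrix(
    countData = m[, c("CT_1", "CT_2", "DK_1", "DK_2")],
    colData = data.frame(condition = factor(c("CT", "CT", "DK", "DK"),
                                            levels = c("CT", "DK"))),
    design = ~condition)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  ref <- DESeq2::results(dds, contrast = c("condition", "DK", "CT"))
  expect_gt(cor(mine$log2fc, ref$log2FoldChange), 0.98)
  # the two routes agree on the induced rows within estimation noise
  expect_lt(max(abs(mine$log2fc[1:10] - ref$log2FoldChange[1:10])), 0.35)
})

test_that("rRNA/tRNA-initiating TSSs and weak rows leave the count matrix", {
  genes <- data.frame(
    gene_id = c("rrn1", "trn1", "cds1"),
    replicon = "chr1", start = c(1000L, 3000L, 5000L),
    end = c(2000L, 3100L, 6000L),
    strand = "+", feature_type = c("rRNA", "tRNA", "CDS"), product = "p",
    stringsAsFactors = FALSE)
  ann <- genome_annotation(genes, c(chr1 = 10000))
  master <- data.frame(
    tss_id = c("t_rrna", "t_trna", "t_cds", "t_weak", "t_anti"),
    replicon = "chr1",
    position = c(950L, 2950L, 4900L, 7000L, 1500L),
    strand = c("+", "+", "+", "+", "-"),
    tss_class = c("nTSS", "nTSS", "gTSS", "nTSS", "aTSS"),
    gene_id = c("rrn1", "trn1", "cds1", NA, "rrn1"),
    CT_1 = c(5000L, 4000L, 400L, 100L, 400L),
    CT_2 = c(5000L, 4000L, 420L, 120L, 380L),
    DK_1 = c(5000L, 4000L, 300L, 100L, 500L),
    DK_2 = c(5000L, 4000L, 310L, 110L, 520L),
    stringsAsFactors = FALSE)
  counts <- build_count_matrix(master, ann)
  # rRNA/tRNA sense TSSs excluded despite huge counts; weak row filtered;
  # the antisense TSS over the rRNA gene stays
  expect_setequal(rownames(counts), c("t_cds", "t_anti"))
})
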