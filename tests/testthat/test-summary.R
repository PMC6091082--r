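test_that("condition overlap sets follow exact set algebra", {
  # CT={a,b}, DK={b}, HL={b,c}, HT={b}
  tss <- data.frame(
    tss_id = c("a", "b", "c"),
    active_CT = c(TRUE, TRUE, FALSE),
    active_DK = c(FALSE, TRUE, FALSE),
    active_HL = c(FALSE, TRUE, TRUE),
    active_HT = c(FALSE, TRUE, FALSE))
  res <- activity_set_analysis(tss)
  expect_equal(res$total, 3)
  expect_equal(res$all_four$count, 1)
  pc <- res$per_condition
  expect_equal(pc$specific[pc$condition == "CT"], 1)
  expect_equal(pc$specific[pc$condition == "HL"], 1)
  expect_equal(pc$specific[pc$condition == "DK"], 0)
  expect_equal(pc$specific[pc$condition == "HT"], 0)
  expect_equal(pc$active, c(2, 1, 2, 1))
})

test_that("overlap percentages reproduce the published arithmetic", {
  res <- activity_set_analysis(counts = list(total = 4808, all_four = 1096,
                                             no_dark = 2110))
  expect_equal(res$all_four$percent, 22.8)
  expect_equal(res$no_dark$percent, 43.9)
})

test_that("brute-force set enumeration agrees on a fixture", {
  fx <- default_fixture()
  cand <- lapply(CONDITIONS, function(cd) call_condition_tss(fx$tracks, cd))
  master <- build_master_table(cand, fx$tracks, calling_params(), fx$genome)
  res <- activity_set_analysis(master)
  act <- lapply(CONDITIONS, function(cd) {
    master$tss_id[master[[paste0("active_", cd)]]]
  })
  names(act) <- CONDITIONS
  expect_equal(res$all_four$count,
               length(Reduce(intersect, act)))
  expect_equal(res$no_dark$count,
               length(Reduce(intersect, act[c("CT", "HL", "HT")])))
  for (cd in CONDITIONS) {
    others <- unlist(act[setdiff(CONDITIONS, cd)])
    expect_equal(res$per_condition$specific[res$per_condition$condition == cd],
                 length(setdiff(act[[cd]], others)))
  }
  # specific + shared partition each condition's active set
  pc <- res$per_condition
  shared <- vapply(CONDITIONS, function(cd) {
    sum(act[[cd]] %in% unlist(act[setdiff(CONDITIONS, cd)]))
  }, 0)
  expect_equal(pc$specific + shared, pc$active, ignore_attr = TRUE)
})

test_that("nucleotide usage counts strand-aware +1 bases per class", {
  tss <- data.frame(
    tss_class = c("gTSS", "gTSS", "aTSS", "nTSS"),
    nucleotide = c("A", "A", "G", "C"))
  res <- nucleotide_usage(tss)
  all_row <- res[res$tss_class == "all", ]
  expect_equal(all_row$percent[all_row$base == "A"], 50.0)
  expect_equal(all_row$percent[all_row$base == "G"], 25.0)
  expect_equal(all_row$percent[all_row$base == "C"], 25.0)
  expect_equal(all_row$percent[all_row$base == "T"], 0.0)
  expect_lt(abs(sum(all_row$percent) - 100), 0.2)
  # computed from the genome when no nucleotide column is present
  tss2 <- data.frame(tss_class = "gTSS", replicon = "chr1",
                     position = 2L, strand = "-")
  res2 <- nucleotide_usage(tss2, genome = c(chr1 = "ACGT"))
  expect_equal(res2$count[res2$tss_class == "all" & res2$base == "G"], 1L)
})

test_that("planted initiation-base composition is recovered end to end", {
  cfg <- sim_config(seed = 13, genome_length = 120000L, n_genes = 70L,
                    n_tss_per_class = c(gTSS = 60L, iTSS = 40L,
                                        aTSS = 60L, nTSS = 40L),
                    start_nucleotide_probs = c(A = 0.6, G = 0.3,
                                               C = 0.05, T = 0.05))
  fx <- simulate_drnaseq(cfg)
  cand <- lapply(CONDITIONS, function(cd) call_condition_tss(fx$tracks, cd))
  master <- build_master_table(cand, fx$tracks, calling_params(), fx$genome)
  master$tss_class <- classify_tss(master$replicon, master$position,
                                   master$strand, fx$annotation)$tss_class
  expect_gte(nrow(master), 190)
  res <- nucleotide_usage(master)
  a_pct <- res$percent[res$tss_class == "all" & res$base == "A"]
  expect_lt(abs(a_pct - 60), 5)
})

test_that("transcript ranking sorts by peak normalized abundance", {
  genes <- data.frame(
    gene_id = c("rrn1", "cds1", "cds2"),
    replicon = "chr1", start = c(1000L, 3000L, 5000L),
    end = c(2000L, 4000L, 6000L),
    strand = "+", feature_type = c("rRNA", "CDS", "CDS"), product = "p",
    stringsAsFactors = FALSE)
  ann <- genome_annotation(genes, c(chr1 = 10000))
  tss <- data.frame(
    tss_id = c("t_rrna", "t_hi", "t_lo"),
    replicon = "chr1", position = c(950L, 2900L, 4900L),
    strand = "+",
    tss_class = c("nTSS", "gTSS", "gTSS"),
    gene_id = c("rrn1", "cds1", "cds2"),
    CT_1 = c(9000L, 100L, 400L), CT_2 = c(9000L, 100L, 400L),
    DK_1 = c(9000L, 900L, 100L), DK_2 = c(9000L, 900L, 100L),
    HL_1 = c(9000L, 100L, 100L), HL_2 = c(9000L, 100L, 100L),
    HT_1 = c(9000L, 100L, 100L), HT_2 = c(9000L, 100L, 100L),
    stringsAsFactors = FALSE)
  sf <- setNames(rep(1, 8), c("CT_1", "CT_2", "DK_1", "DK_2",
                              "HL_1", "HL_2", "HT_1", "HT_2"))
  ranked <- rank_transcripts(tss, sf, ann)
  # the huge rRNA-initiating TSS is excluded entirely
  expect_false("t_rrna" %in% ranked$tss_id)
  expect_equal(ranked$tss_id, c("t_hi", "t_lo"))
  expect_equal(ranked$max_condition, c("DK", "CT"))
  # ties order stably by tss_id
  tss2 <- tss[tss$tss_id != "t_rrna", ]
  tss2[, c("CT_1", "CT_2", "DK_1", "DK_2",
           "HL_1", "HL_2", "HT_1", "HT_2")] <- 100L
  ranked2 <- rank_transcripts(tss2, sf, ann)
  expect_equal(ranked2$tss_id, sort(ranked2$tss_id))
})

test_that("inverse-regulation query pairs opposite-sign asRNA and mRNA", {
  tss <- data.frame(
    tss_id = c("g_tss", "a_tss"),
    tss_class = c("gTSS", "aTSS"),
    gene_id = c("cds1", "cds1"),
    stringsAsFactors = FALSE)
  det <- data.frame(
    tss_id = c("g_tss", "a_tss"),
    contrast = "DK/CT",
    base_mean = 100,
    log2fc = c(-2.5, 3.1),
    p_value = c(1e-8, 1e-9),
    padj = c(1e-7, 1e-8),
    is_det = c(TRUE, TRUE),
    stringsAsFactors = FALSE)
  pairs <- inverse_regulation_pairs(tss, det)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$gene_id, "cds1")
  det$log2fc <- c(2.5, 3.1)  # same sign: no pair
  expect_equal(nrow(inverse_regulation_pairs(tss, det)), 0L)
})
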