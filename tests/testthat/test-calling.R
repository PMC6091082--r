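# small hand-built two-replicate condition for rule-level checks
mini_tracks <- function(primary1, primary2, minus1, minus2, L = 100L) {
  mk <- function(v, type, r) {
    five_prime_track(list(chr1 = list("+" = v, "-" = integer(L))),
                     type, "CT", r)
  }
  list(CT_1_primary = mk(primary1, "primary", 1),
       CT_2_primary = mk(primary2, "primary", 2),
       CT_1_minus = mk(minus1, "minus", 1),
       CT_2_minus = mk(minus2, "minus", 2))
}

vec_with <- function(L, at, values) {
  v <- integer(L); v[at] <- as.integer(values); v
}

test_that("enrichment is the pseudocounted ratio of replicate sums", {
  expect_equal(compute_enrichment(c(400, 450), c(10, 12)), 851 / 23)
  expect_equal(compute_enrichment(c(0, 0), c(5, 5)), 1 / 11)
  expect_equal(compute_enrichment(c(100, 100), c(0, 0)), 201)
  # symmetric in replicate order
  expect_equal(compute_enrichment(c(450, 400), c(12, 10)), 851 / 23)
  expect_error(compute_enrichment(c(1, 2), c(1, 2, 3)), "replicate")
})

test_that("a position needs every replicate above threshold and enrichment", {
  L <- 100L
  tr <- mini_tracks(vec_with(L, c(10, 30), c(400, 300)),
                    vec_with(L, c(10, 30), c(450, 2)),
                    vec_with(L, c(10, 30), c(10, 0)),
                    vec_with(L, c(10, 30), c(12, 0)))
  cand <- call_condition_tss(tr, "CT")
  # position 10 passes; position 30 fails replicate consistency (300, 2)
  expect_equal(cand$position, 10L)
  expect_equal(cand$enrichment, 851 / 23)
})

test_that("enrichment below threshold blocks the call", {
  L <- 100L
  tr <- mini_tracks(vec_with(L, 10, 100), vec_with(L, 10, 100),
                    vec_with(L, 10, 80), vec_with(L, 10, 80))
  expect_equal(nrow(call_condition_tss(tr, "CT")), 0L)
})

test_that("clustered positions collapse to the strongest, ties upstream", {
  L <- 100L
  tr <- mini_tracks(vec_with(L, c(10, 12), c(400, 250)),
                    vec_with(L, c(10, 12), c(400, 250)),
                    integer(L), integer(L))
  cand <- call_condition_tss(tr, "CT")
  expect_equal(cand$position, 10L)  # summed 800 beats 500, 2 bp apart
  # exact tie: most upstream (smallest position on +) wins
  tr <- mini_tracks(vec_with(L, c(20, 22), c(300, 300)),
                    vec_with(L, c(20, 22), c(300, 300)),
                    integer(L), integer(L))
  expect_equal(call_condition_tss(tr, "CT")$position, 20L)
})

test_that("a missing minus replicate is reported", {
  L <- 50L
  tr <- mini_tracks(integer(L), integer(L), integer(L), integer(L))
  tr$CT_2_minus <- NULL
  expect_error(call_condition_tss(tr, "CT"), "minus")
})

test_that("raising min_enrichment never enlarges the called set", {
  fx <- default_fixture()
  thresholds <- c(1.5, 2, 4, 8, 20)
  sets <- lapply(thresholds, function(th) {
    cand <- call_condition_tss(fx$tracks, "CT",
                               calling_params(min_enrichment = th))
    paste(cand$position, cand$strand)
  })
  for (i in seq_along(sets)[-1]) {
    expect_true(all(sets[[i]] %in% sets[[i - 1]]))
  }
})

test_that("mirrored fixtures give exactly mirrored calls", {
  fx <- default_fixture()
  L <- fx$config$genome_length
  mirrored <- lapply(fx$tracks, mirror_track, L = L)
  orig <- call_condition_tss(fx$tracks, "DK")
  mirr <- call_condition_tss(mirrored, "DK")
  flip <- data.frame(position = L + 1L - mirr$position,
                     strand = ifelse(mirr$strand == "+", "-", "+"))
  key <- function(d) sort(paste(d$position, d$strand))
  expect_identical(key(flip), key(orig))
})

test_that("master table activity follows the raw-read threshold per condition", {
  L <- 200L
  mk <- function(cond, r, type, at, val) {
    five_prime_track(list(chr1 = list("+" = vec_with(L, at, val),
                                      "-" = integer(L))), type, cond, r)
  }
  tracks <- list()
  for (cond in CONDITIONS) {
    # TSS at 50: strong only in DK (sum 350); elsewhere 20
    # TSS at 120: 299 raw reads everywhere -> never active
    v_50 <- if (cond == "DK") c(200, 150) else c(10, 10)
    for (r in 1:2) {
      tracks[[paste0(cond, "_", r, "_primary")]] <-
        mk(cond, r, "primary", c(50, 120), c(v_50[r], c(150, 149)[r]))
      tracks[[paste0(cond, "_", r, "_minus")]] <-
        mk(cond, r, "minus", c(50, 120), c(0, 0))
    }
  }
  cand <- lapply(CONDITIONS, function(cd) call_condition_tss(tracks, cd))
  master <- build_master_table(cand, tracks)
  row50 <- master[master$position == 50, ]
  expect_equal(row50$active_conditions, "DK")
  expect_true(row50$active_DK)
  expect_false(row50$active_CT)
  # 299 raw reads in every condition: dropped from the master set
  expect_false(120 %in% master$position)
})

test_that("the master set is the union of per-condition candidates", {
  fx <- default_fixture()
  cand <- lapply(CONDITIONS, function(cd) call_condition_tss(fx$tracks, cd))
  master <- build_master_table(cand, fx$tracks, calling_params(), fx$genome)
  union_keys <- unique(unlist(lapply(cand, function(d) {
    paste(d$replicon, d$position, d$strand)
  })))
  master_keys <- paste(master$replicon, master$position, master$strand)
  active_any <- rowSums(as.matrix(
    master[, paste0("active_", CONDITIONS)])) > 0
  expect_true(all(master_keys %in% union_keys))
  expect_true(all(active_any))
  # initiation nucleotide matches the planted truth at recovered positions
  m <- match(paste(master$position, master$strand),
             paste(fx$truth$position, fx$truth$strand))
  expect_equal(master$nucleotide[!is.na(m)], fx$truth$init_nt[m[!is.na(m)]])
})

test_that("planted TSSs are recovered with few false calls", {
  fx <- default_fixture()
  cand <- lapply(CONDITIONS, function(cd) call_condition_tss(fx$tracks, cd))
  master <- build_master_table(cand, fx$tracks, calling_params(), fx$genome)
  rec <- planted_tss_recovery(fx$truth, master)
  expect_gte(rec$recall, 0.95)
  expect_lte(rec$false_calls_per_10kb, 1)
})
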