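# Shared fixtures, built once per test run.

fixture_cache <- new.env(parent = emptyenv())

# default study-condition fixture: 50 kb genome, 60 planted TSSs
default_fixture <- function() {
  if (is.null(fixture_cache$default)) {
    fixture_cache$default <- simulate_drnaseq(sim_config(seed = 101))
  }
  fixture_cache$default
}

# toy one-gene annotation used for rule-level classification checks
toy_annotation <- function(genes = NULL, length = 10000) {
  if (is.null(genes)) {
    genes <- data.frame(
      gene_id = "g1", replicon = "chr1", start = 1000L, end = 2000L,
      strand = "+", feature_type = "CDS", product = "p1",
      stringsAsFactors = FALSE)
  }
  genome_annotation(genes, c(chr1 = length))
}

# Independent brute-force classification oracle: scalar logic, every gene
# checked against every rule exhaustively, precedence applied at the end.
oracle_classify <- function(replicon, position, strand, annotation,
                            upstream_window = 200, antisense_flank = 50) {
  genes <- annotation$genes
  n <- length(position)
  replicon <- rep_len(replicon, n)
  strand <- rep_len(strand, n)
  out <- character(n)
  gene <- character(n)
  for (i in seq_len(n)) {
    g_hit <- NULL; g_d <- Inf
    i_hit <- NULL
    a_hit <- NULL; a_gap <- Inf
    n_hit <- NULL; n_d <- Inf
    for (k in seq_len(nrow(genes))) {
      g <- genes[k, ]
      if (g$replicon != replicon[i]) next
      d <- if (g$strand == "+") g$start - position[i] else position[i] - g$end
      inside <- position[i] >= g$start && position[i] <= g$end
      if (g$strand == strand[i]) {
        if (g$feature_type == "CDS") {
          if (d >= 0 && d <= upstream_window && d < g_d) {
            g_hit <- g$gene_id; g_d <- d
          }
          if (inside && is.null(i_hit)) i_hit <- g$gene_id
        } else {
          dd <- if (inside) 0 else d
          if (((d >= 0 && d <= upstream_window) || inside) && dd < n_d) {
            n_hit <- g$gene_id; n_d <- dd
          }
        }
      } else {
        if (position[i] >= g$start - antisense_flank &&
            position[i] <= g$end + antisense_flank) {
          gap <- max(g$start - position[i], position[i] - g$end, 0)
          if (gap < a_gap) { a_hit <- g$gene_id; a_gap <- gap }
        }
      }
    }
    if (!is.null(g_hit)) { out[i] <- "gTSS"; gene[i] <- g_hit }
    else if (!is.null(i_hit)) { out[i] <- "iTSS"; gene[i] <- i_hit }
    else if (!is.null(a_hit)) { out[i] <- "aTSS"; gene[i] <- a_hit }
    else { out[i] <- "nTSS"; gene[i] <- if (is.null(n_hit)) NA else n_hit }
  }
  data.frame(tss_class = out, gene_id = gene, stringsAsFactors = FALSE)
}

# null count matrix: 4 conditions x 2 replicates, no planted effects
null_count_matrix <- function(seed, n = 500, mu = 500, alpha = 0.05) {
  set.seed(seed)
  matrix(rnbinom(n * 8L, mu = mu, size = 1 / alpha), nrow = n,
         dimnames = list(sprintf("t%04d", seq_len(n)),
                         c("CT_1", "CT_2", "DK_1", "DK_2",
                           "HL_1", "HL_2", "HT_1", "HT_2")))
}

# mirror a fixture: flip coordinates p -> L + 1 - p and swap strands
mirror_track <- function(track, L) {
  counts <- lapply(track$counts, function(r) {
    list("+" = rev(r[["-"]]), "-" = rev(r[["+"]]))
  })
  five_prime_track(counts, track$type, track$condition, track$replicate)
}
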