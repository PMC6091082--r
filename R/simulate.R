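#' Configuration for the synthetic dRNA-Seq fixture generator
#'
#' The generator emulates the statistical structure the downstream analysis
#' assumes: planted TSS positions with condition-dependent negative-binomial
#' 5'-end counts in the TEX-treated (primary) libraries, the same counts
#' attenuated by `tex_enrichment` in the untreated (minus) control
#' libraries, a uniform position-wise Poisson background of processed 5'
#' ends in both library types, and a non-overlapping gene annotation with
#' sense, antisense and intergenic TSS placements. Four growth conditions
#' (CT, DK, HL, HT) with two replicates each mirror the study design.
#'
#' @param genome_length replicon length in bp.
#' @param n_genes number of gene features to place (non-overlapping).
#' @param gene_length_range min/max gene length in bp.
#' @param n_tss_per_class named counts of TSSs to plant per class
#'   (`gTSS`, `iTSS`, `aTSS`, `nTSS`).
#' @param base_mean expected primary-library 5'-end count at a true TSS
#'   under the control condition.
#' @param dispersion negative-binomial dispersion alpha
#'   (variance = mu + alpha * mu^2); 0 gives Poisson counts.
#' @param tex_enrichment ratio of primary to minus expected counts at true
#'   TSSs; must exceed 1 for the contrast to be informative.
#' @param background_rate expected count per background position (both
#'   library types).
#' @param de_fraction fraction of planted TSSs given a differential effect
#'   in one random non-control condition (ignored when `planted_lfc_table`
#'   is supplied).
#' @param effect_lfc magnitude of the planted log2 fold change.
#' @param planted_lfc_table optional data.frame `tss_id`, `condition`,
#'   `lfc` overriding the random effect assignment (`tss_id` as
#'   `tss_0001`... in planting order).
#' @param utr_length_distribution function(n) returning n integer 5'-UTR
#'   lengths for planted gTSSs. The default draws from a rounded log-normal
#'   with median 52 nt, capped at 200.
#' @param start_nucleotide_probs sampling weights for the initiation
#'   nucleotide written into the genome at each planted TSS.
#' @param replicates_per_condition replicates per condition per library type.
#' @param replicon_name name of the single simulated replicon.
#' @param seed mandatory integer seed; there is no global-state fallback.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 50000L,
                       n_genes = 40L,
                       gene_length_range = c(400L, 1200L),
                       n_tss_per_class = c(gTSS = 30L, iTSS = 10L,
                                           aTSS = 15L, nTSS = 5L),
                       base_mean = 500,
                       dispersion = 0.05,
                       tex_enrichment = 10,
                       background_rate = 0.05,
                       de_fraction = 0.3,
                       effect_lfc = 2,
                       planted_lfc_table = NULL,
                       utr_length_distribution = function(n) {
                         pmin(200L, pmax(0L, as.integer(round(
                           rlnorm(n, meanlog = log(52), sdlog = 0.5)))))
                       },
                       start_nucleotide_probs = c(A = 0.523, G = 0.356,
                                                  C = 0.060, T = 0.061),
                       replicates_per_condition = 2L,
                       replicon_name = "chr",
                       seed) {
  if (missing(seed)) stop("a seed is mandatory in sim_config()")
  stopifnot(tex_enrichment > 1, background_rate >= 0, dispersion >= 0,
            genome_length > 0, n_genes > 0, replicates_per_condition >= 1)
  if (!all(TSS_CLASSES %in% names(n_tss_per_class))) {
    stop("n_tss_per_class needs entries for ", paste(TSS_CLASSES, collapse = ", "))
  }
  structure(list(
    genome_length = as.integer(genome_length),
    n_genes = as.integer(n_genes),
    gene_length_range = as.integer(gene_length_range),
    n_tss_per_class = n_tss_per_class[TSS_CLASSES],
    base_mean = base_mean,
    dispersion = dispersion,
    tex_enrichment = tex_enrichment,
    background_rate = background_rate,
    de_fraction = de_fraction,
    effect_lfc = effect_lfc,
    planted_lfc_table = planted_lfc_table,
    utr_length_distribution = utr_length_distribution,
    start_nucleotide_probs = start_nucleotide_probs,
    replicates_per_condition = as.integer(replicates_per_condition),
    replicon_name = replicon_name,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# independent sub-streams per stage so adding draws in one stage does not
# shift every later stage; all offsets stay far below 2^31
stage_seed <- function(config, stage) {
  offset <- c(genome = 11L, plant = 23L, counts = 37L)[[stage]]
  (config$seed %% 100000000L) * 7L + offset
}

#' Generate a random genome and non-overlapping gene annotation
#'
#' Places `n_genes` stranded genes separated by intergenic gaps, including
#' one rRNA, one tRNA and one ncRNA feature so that the non-coding
#' exclusion rules downstream are exercised. Deterministic given the seed.
#'
#' @param config a [sim_config].
#' @return list with `genome` (named character vector) and `annotation`
#'   (a [genome_annotation]).
#' @export
generate_genome_and_annotation <- function(config) {
  set.seed(stage_seed(config, "genome"))
  L <- config$genome_length
  n <- config$n_genes
  min_gap <- 150L  # leaves room for upstream windows and intergenic TSSs
  lens <- sample(config$gene_length_range[1]:config$gene_length_range[2],
                 n, replace = TRUE)
  needed <- sum(lens) + (n + 1L) * min_gap
  if (needed > L) {
    stop("genome too short to place ", n, " genes without overlap: needs >= ",
         needed, " bp, have ", L)
  }
  slack <- L - sum(lens) - (n + 1L) * min_gap
  # split the slack over the n+1 gaps at random
  cuts <- sort(sample.int(slack + 1L, n, replace = TRUE) - 1L)
  extra <- diff(c(0L, cuts, slack))
  gaps <- min_gap + extra
  starts <- cumsum(gaps[seq_len(n)]) + c(0L, cumsum(lens))[seq_len(n)] + 1L
  ends <- starts + lens - 1L
  strand <- sample(c("+", "-"), n, replace = TRUE)
  # make sure both strands are present
  if (length(unique(strand)) == 1L) strand[1] <- setdiff(c("+", "-"), strand[1])
  feature_type <- rep("CDS", n)
  special <- sample.int(n, 3L)
  feature_type[special] <- c("rRNA", "tRNA", "ncRNA")
  genes <- data.frame(
    gene_id = sprintf("g%03d", seq_len(n)),
    replicon = config$replicon_name,
    start = starts, end = ends, strand = strand,
    feature_type = feature_type,
    product = ifelse(feature_type == "CDS", "hypothetical protein",
                     feature_type),
    stringsAsFactors = FALSE
  )
  # GC-rich background typical of cyanobacterial genomes
  genome_chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                         prob = c(0.23, 0.27, 0.27, 0.23))
  genome <- setNames(paste(genome_chars, collapse = ""), config$replicon_name)
  replicons <- setNames(as.numeric(L), config$replicon_name)
  list(genome = genome, annotation = genome_annotation(genes, replicons))
}

#' Plant a ground-truth TSS set
#'
#' Places exactly the requested number of TSSs per class such that
#' re-classifying the planted coordinates with [classify_tss] reproduces
#' the planted class for every record. gTSSs get a 5'-UTR length drawn from
#' the configured distribution; when the nTSS quota allows, one nTSS is
#' placed in front of the rRNA and one in front of the tRNA feature so the
#' downstream rRNA/tRNA exclusion filter has work to do. Per-condition
#' expected counts follow the planted log2 fold changes relative to CT.
#'
#' @param config a [sim_config].
#' @param annotation the annotation from [generate_genome_and_annotation].
#' @return data.frame of truth records (`tss_id`, `replicon`, `position`,
#'   `strand`, `true_class`, `gene_id`, `utr_length`, `init_nt`,
#'   `mean_<condition>` and `lfc_<condition>` columns), with the replicon
#'   length table attached as attribute `replicons`.
#' @export
plant_tss_truth <- function(config, annotation) {
  set.seed(stage_seed(config, "plant"))
  genes <- annotation$genes
  L <- config$genome_length
  params <- classification_params()
  min_sep <- 10L  # keeps planted TSSs out of each other's cluster windows

  # exhaustive class map of every (position, strand)
  all_pos <- rep(seq_len(L), 2L)
  all_strand <- rep(c("+", "-"), each = L)
  cls <- classify_tss(config$replicon_name, all_pos, all_strand, annotation,
                      params)

  taken <- integer(0)
  ok_spacing <- function(p) all(abs(taken - p) >= min_sep)

  pick_from_pool <- function(pool_idx, n_wanted, must_idx = integer(0)) {
    chosen <- integer(0)
    for (i in must_idx) {
      if (ok_spacing(all_pos[i])) {
        chosen <- c(chosen, i)
        taken <<- c(taken, all_pos[i])
      }
    }
    pool_idx <- setdiff(pool_idx, chosen)
    pool_idx <- sample(pool_idx)
    for (i in pool_idx) {
      if (length(chosen) >= n_wanted) break
      if (ok_spacing(all_pos[i])) {
        chosen <- c(chosen, i)
        taken <<- c(taken, all_pos[i])
      }
    }
    if (length(chosen) < n_wanted) {
      stop("could not place ", n_wanted, " TSSs of the requested class; ",
           "genome has too little eligible space")
    }
    chosen[seq_len(n_wanted)]
  }

  quota <- config$n_tss_per_class

  # --- gTSS: anchored to CDS genes with a drawn UTR length -----------------
  n_g <- quota[["gTSS"]]
  cds <- genes[genes$feature_type == "CDS", ]
  if (nrow(cds) == 0L) stop("no CDS genes to anchor gTSSs")
  g_rows <- list()
  gene_order <- sample(rep_len(seq_len(nrow(cds)), max(4L * n_g, nrow(cds))))
  gi <- 1L
  while (length(g_rows) < n_g) {
    if (gi > length(gene_order)) stop("could not place all gTSSs")
    g <- cds[gene_order[gi], ]; gi <- gi + 1L
    placed <- FALSE
    for (attempt in seq_len(30L)) {
      u <- config$utr_length_distribution(1L)
      p <- if (g$strand == "+") g$start - u else g$end + u
      if (p < 1L || p > L || !ok_spacing(p)) next
      cl <- classify_tss(config$replicon_name, p, g$strand, annotation, params)
      if (cl$tss_class == "gTSS" && cl$gene_id == g$gene_id) {
        g_rows[[length(g_rows) + 1L]] <-
          data.frame(position = p, strand = g$strand, true_class = "gTSS",
                     gene_id = g$gene_id, utr_length = u,
                     stringsAsFactors = FALSE)
        taken <- c(taken, p)
        placed <- TRUE
        break
      }
    }
    if (!placed) next
  }
  truth <- do.call(rbind, g_rows)

  # --- iTSS / aTSS / nTSS: sampled from the exhaustive class pools ---------
  add_class <- function(truth, class, must_idx = integer(0)) {
    n_wanted <- quota[[class]]
    if (n_wanted == 0L) return(truth)
    pool <- which(cls$tss_class == class)
    if (length(pool) == 0L) {
      stop("no eligible positions for class ", class,
           " (no intergenic space)" )
    }
    idx <- pick_from_pool(pool, n_wanted, must_idx)
    rbind(truth, data.frame(
      position = all_pos[idx], strand = all_strand[idx], true_class = class,
      gene_id = cls$gene_id[idx], utr_length = NA_integer_,
      stringsAsFactors = FALSE))
  }
  truth <- add_class(truth, "iTSS")
  truth <- add_class(truth, "aTSS")
  # try to seat nTSSs in front of the rRNA and tRNA features first
  nc_ids <- genes$gene_id[genes$feature_type %in% c("rRNA", "tRNA")]
  must <- integer(0)
  if (quota[["nTSS"]] >= length(nc_ids)) {
    for (id in nc_ids) {
      cand <- which(cls$tss_class == "nTSS" & !is.na(cls$gene_id) &
                      cls$gene_id == id)
      if (length(cand)) must <- c(must, sample(cand, 1L))
    }
  }
  truth <- add_class(truth, "nTSS", must_idx = must)

  # --- expression truth ----------------------------------------------------
  n_tss <- nrow(truth)
  truth$tss_id <- sprintf("tss_%04d", seq_len(n_tss))
  truth$replicon <- config$replicon_name
  lfc <- matrix(0, n_tss, 3L, dimnames = list(truth$tss_id, c("DK", "HL", "HT")))
  if (!is.null(config$planted_lfc_table)) {
    tab <- config$planted_lfc_table
    for (r in seq_len(nrow(tab))) {
      lfc[tab$tss_id[r], tab$condition[r]] <- tab$lfc[r]
    }
  } else if (config$de_fraction > 0) {
    hit <- runif(n_tss) < config$de_fraction
    cond <- sample(c("DK", "HL", "HT"), n_tss, replace = TRUE)
    sign <- sample(c(-1, 1), n_tss, replace = TRUE)
    for (i in which(hit)) {
      lfc[i, cond[i]] <- sign[i] * config$effect_lfc
    }
  }
  truth$lfc_DK <- lfc[, "DK"]; truth$lfc_HL <- lfc[, "HL"]
  truth$lfc_HT <- lfc[, "HT"]
  truth$mean_CT <- config$base_mean
  truth$mean_DK <- config$base_mean * 2^lfc[, "DK"]
  truth$mean_HL <- config$base_mean * 2^lfc[, "HL"]
  truth$mean_HT <- config$base_mean * 2^lfc[, "HT"]
  truth$init_nt <- sample(names(config$start_nucleotide_probs), n_tss,
                          replace = TRUE, prob = config$start_nucleotide_probs)
  cols <- c("tss_id", "replicon", "position", "strand", "true_class",
            "gene_id", "utr_length", "init_nt",
            paste0("mean_", CONDITIONS), paste0("lfc_", c("DK", "HL", "HT")))
  truth <- truth[, cols]
  rownames(truth) <- NULL
  attr(truth, "replicons") <- annotation$replicons
  truth
}

# overwrite the genome base at each planted TSS so the strand-aware
# initiation nucleotide matches the truth record
apply_start_nucleotides <- function(genome, truth) {
  for (rep_name in unique(truth$replicon)) {
    seq_chars <- strsplit(genome[[rep_name]], "")[[1]]
    rows <- truth[truth$replicon == rep_name, ]
    base <- ifelse(rows$strand == "+", rows$init_nt,
                   chartr("ACGT", "TGCA", rows$init_nt))
    seq_chars[rows$position] <- base
    genome[[rep_name]] <- paste(seq_chars, collapse = "")
  }
  genome
}

#' Simulate 5'-end count tracks for every library
#'
#' For each condition x replicate x library type, counts at planted TSS
#' positions are negative-binomial with the condition's planted mean
#' (divided by `tex_enrichment` in the minus libraries) on top of a
#' position-wise Poisson background present in both library types.
#' Deterministic given the config seed.
#'
#' @param truth the truth table from [plant_tss_truth].
#' @param config a [sim_config].
#' @return Named list of [five_prime_track] objects, one per library,
#'   named `<condition>_<replicate>_<type>`.
#' @export
simulate_library_counts <- function(truth, config) {
  set.seed(stage_seed(config, "counts"))
  replicons <- attr(truth, "replicons")
  if (is.null(replicons)) {
    stop("truth table lacks the 'replicons' attribute from plant_tss_truth()")
  }
  size <- if (config$dispersion > 0) 1 / config$dispersion else Inf
  draw <- function(mu, n) {
    if (is.finite(size)) rnbinom(n, mu = mu, size = size) else rpois(n, mu)
  }
  tracks <- list()
  for (cond in CONDITIONS) {
    mu_tss <- truth[[paste0("mean_", cond)]]
    for (r in seq_len(config$replicates_per_condition)) {
      for (type in c("primary", "minus")) {
        mu <- if (type == "primary") mu_tss else mu_tss / config$tex_enrichment
        counts <- lapply(replicons, function(len) {
          list("+" = rpois(len, config$background_rate),
               "-" = rpois(len, config$background_rate))
        })
        signal <- draw(mu, nrow(truth))
        for (i in seq_len(nrow(truth))) {
          rn <- truth$replicon[i]; s <- truth$strand[i]; p <- truth$position[i]
          counts[[rn]][[s]][p] <- counts[[rn]][[s]][p] + signal[i]
        }
        tracks[[library_name(type, cond, r)]] <-
          five_prime_track(counts, type, cond, r)
      }
    }
  }
  tracks
}

#' Generate a complete synthetic dRNA-Seq fixture
#'
#' Runs genome generation, TSS planting and count simulation, and
#' optionally writes the fixture bundle (genome FASTA, annotation GFF3, one
#' bedGraph pair per library, truth TSV) to a directory. Byte-identical
#' output for identical config and seed.
#'
#' @param config a [sim_config].
#' @param dir optional output directory (created if missing).
#' @return list with `genome`, `annotation`, `truth`, `tracks`, `config`.
#' @export
simulate_drnaseq <- function(config, dir = NULL) {
  ga <- generate_genome_and_annotation(config)
  truth <- plant_tss_truth(config, ga$annotation)
  genome <- apply_start_nucleotides(ga$genome, truth)
  tracks <- simulate_library_counts(truth, config)
  fixture <- list(genome = genome, annotation = ga$annotation,
                  truth = truth, tracks = tracks, config = config)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_genome_fasta(genome, file.path(dir, "genome.fa"))
    write_gff3(ga$annotation, file.path(dir, "annotation.gff3"))
    truth_out <- truth
    write.table(truth_out, file.path(dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    for (tr in tracks) write_track_bedgraphs(tr, dir)
  }
  fixture
}
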