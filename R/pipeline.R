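#' Run the full primary-transcriptome pipeline
#'
#' Orchestrates all stages: fixture simulation (or loading of real
#' inputs), per-condition TSS calling, master-table construction,
#' positional classification, 5'-UTR annotation, differential expression
#' and condition summaries, writing every result table plus a JSON run
#' manifest to the output directory. Given the same configuration and
#' seed, the output files are byte-identical across runs.
#'
#' The configuration is a YAML file (or an equivalent named list) with the
#' blocks:
#' \preformatted{
#' output_dir: out/            # may also be passed as an argument
#' simulate: true              # use the synthetic generator ...
#' simulation: {seed: 1, genome_length: 50000, ...}   # sim_config() fields
#' inputs:                     # ... or real inputs instead
#'   genome: genome.fa
#'   annotation: annotation.gff3
#'   tracks_dir: tracks/       # <cond>_<rep>_<type>_<fwd|rev>.bedgraph
#'   conditions: [CT, DK, HL, HT]
#'   replicates: 2
#' calling:        {min_enrichment: 2, min_raw_reads_activity: 300, ...}
#' classification: {upstream_window: 200, antisense_flank: 50}
#' differential:   {min_max_count: 300, lfc_threshold: 1, padj_threshold: 0.01}
#' homolog_evidence: evidence.tsv   # optional
#' top_n: 20
#' }
#'
#' @param config path to a YAML config file, or a named list.
#' @param output_dir overrides `output_dir` from the config.
#' @return (invisibly) list with all in-memory stage results and
#'   `output_dir`.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  out_dir <- output_dir %||% config$output_dir
  if (is.null(out_dir)) stop("no output directory given")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  cal_par <- do.call(calling_params, config$calling %||% list())
  cls_par <- do.call(classification_params, config$classification %||% list())
  de_cfg <- config$differential %||% list()

  manifest <- list(
    package_version = as.character(utils::packageVersion("drnatss")),
    parameters = list(calling = unclass(cal_par),
                      classification = unclass(cls_par),
                      differential = de_cfg),
    stages = list()
  )

  # --- stage 1: inputs -----------------------------------------------------
  if (isTRUE(config$simulate)) {
    sim_args <- config$simulation %||% list()
    if (is.null(sim_args$seed)) stop("simulation block needs a seed")
    cfg <- do.call(sim_config, sim_args)
    fixture <- simulate_drnaseq(cfg, dir = file.path(out_dir, "fixture"))
    genome <- fixture$genome
    annotation <- fixture$annotation
    tracks <- fixture$tracks
    manifest$seed <- cfg$seed
    manifest$stages$simulate <- list(
      n_genes = nrow(annotation$genes),
      n_planted_tss = nrow(fixture$truth)
    )
  } else {
    inp <- config$inputs
    if (is.null(inp)) stop("config needs either simulate: true or an inputs block")
    for (f in c("genome", "annotation")) {
      if (is.null(inp[[f]]) || !file.exists(inp[[f]])) {
        stop("missing input file: ", f, " (", inp[[f]] %||% "unset", ")")
      }
    }
    genome <- read_genome_fasta(inp$genome)
    annotation <- read_gff3(inp$annotation)
    conds <- inp$conditions %||% CONDITIONS
    n_rep <- inp$replicates %||% 2L
    tracks <- list()
    missing_libs <- character(0)
    for (cond in conds) {
      for (r in seq_len(n_rep)) {
        for (type in c("primary", "minus")) {
          stem <- file.path(inp$tracks_dir, library_name(type, cond, r))
          fwd <- paste0(stem, "_fwd.bedgraph")
          rev <- paste0(stem, "_rev.bedgraph")
          if (!file.exists(fwd) || !file.exists(rev)) {
            missing_libs <- c(missing_libs, library_name(type, cond, r))
            next
          }
          tracks[[library_name(type, cond, r)]] <- read_bedgraph_pair(
            fwd, rev, type, cond, r, annotation$replicons)
        }
      }
    }
    if (length(missing_libs)) {
      stop("missing library track file(s): ",
           paste(missing_libs, collapse = ", "))
    }
    manifest$input_checksums <- as.list(tools::md5sum(
      c(inp$genome, inp$annotation)))
    fixture <- NULL
  }
  conds_present <- sort(unique(vapply(tracks, function(t) t$condition, "")))
  conds_present <- CONDITIONS[CONDITIONS %in% conds_present]

  # --- stage 2: calling ----------------------------------------------------
  candidates <- lapply(conds_present, function(cond) {
    call_condition_tss(tracks, cond, cal_par)
  })
  names(candidates) <- conds_present
  master <- build_master_table(candidates, tracks, cal_par, genome)
  manifest$stages$calling <- list(
    candidates_per_condition = lapply(candidates, nrow),
    master_tss = nrow(master)
  )

  # --- stage 3: classification --------------------------------------------
  cls <- classify_tss(master$replicon, master$position, master$strand,
                      annotation, cls_par)
  master$tss_class <- cls$tss_class
  master$gene_id <- cls$gene_id
  class_summary <- summarize_classes(master)
  manifest$stages$classification <- as.list(
    setNames(class_summary$count, class_summary$tss_class))

  # --- stage 4: UTR / leaderless ------------------------------------------
  evidence <- NULL
  if (!is.null(config$homolog_evidence)) {
    evidence <- read.delim(config$homolog_evidence, stringsAsFactors = FALSE)
  }
  master <- annotate_utrs(master, annotation, evidence)
  utr_stats <- utr_statistics(master$utr_length[master$tss_class == "gTSS"])
  manifest$stages$utr <- list(n_gtss = utr_stats$n,
                              median_utr_nt = utr_stats$median)

  # --- stage 5: differential expression ------------------------------------
  de <- run_differential_expression(
    master, annotation,
    min_max_count = de_cfg$min_max_count %||% 300,
    lfc_threshold = de_cfg$lfc_threshold %||% 1,
    padj_threshold = de_cfg$padj_threshold %||% 0.01)
  manifest$stages$differential <- list(
    tested_tss = nrow(de$counts),
    det_per_contrast = as.list(tapply(de$results$is_det,
                                      de$results$contrast, sum))
  )

  # --- stage 6: summaries --------------------------------------------------
  overlap <- activity_set_analysis(master)
  nt_usage <- nucleotide_usage(master, genome)
  ranked <- rank_transcripts(master, de$size_factors, annotation,
                             det_results = de$results,
                             top_n = config$top_n %||% 20)

  # --- outputs -------------------------------------------------------------
  w <- function(x, name) {
    write.table(x, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  master_out <- master
  for (ct in unique(de$results$contrast)) {
    sub <- de$results[de$results$contrast == ct, ]
    suffix <- gsub("/", "_vs_", ct)
    m <- match(master_out$tss_id, sub$tss_id)
    master_out[[paste0("log2fc_", suffix)]] <- sub$log2fc[m]
    master_out[[paste0("padj_", suffix)]] <- sub$padj[m]
  }
  write_tss_table(master_out, file.path(out_dir, "master_tss.tsv"),
                  gff3_path = file.path(out_dir, "master_tss.gff3"),
                  replicons = annotation$replicons)
  w(de$results, "det_results.tsv")
  w(class_summary, "class_summary.tsv")
  w(overlap$per_condition, "condition_overlap.tsv")
  w(nt_usage, "nucleotide_usage.tsv")
  w(ranked, "ranked_transcripts.tsv")
  w(utr_stats$histogram, "utr_histogram.tsv")
  if (!is.null(fixture)) {
    recovery <- planted_tss_recovery(fixture$truth, master,
                                     cal_par$cluster_window)
    manifest$stages$recovery <- recovery
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(
    output_dir = out_dir, master = master, candidates = candidates,
    class_summary = class_summary, utr_stats = utr_stats, de = de,
    overlap = overlap, nucleotide_usage = nt_usage, ranked = ranked,
    fixture = fixture, manifest = manifest
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Recovery of planted TSSs by the calling stage
#'
#' Matches planted truth positions against a called master table within a
#' tolerance window and reports recall and the false-call rate.
#'
#' @param truth truth table from [plant_tss_truth].
#' @param master master TSS table from [build_master_table].
#' @param tolerance maximal bp offset for a match (default 3, the cluster
#'   window).
#' @return list with `recall`, `n_true`, `n_called`, `false_calls`,
#'   `false_calls_per_10kb`.
#' @export
planted_tss_recovery <- function(truth, master, tolerance = 3L) {
  matched <- logical(nrow(truth))
  used <- rep(FALSE, nrow(master))
  for (i in seq_len(nrow(truth))) {
    hit <- which(!used &
                   master$replicon == truth$replicon[i] &
                   master$strand == truth$strand[i] &
                   abs(master$position - truth$position[i]) <= tolerance)
    if (length(hit)) {
      matched[i] <- TRUE
      used[hit[1]] <- TRUE
    }
  }
  replicons <- attr(truth, "replicons")
  genome_bp <- if (!is.null(replicons)) sum(replicons) else NA_real_
  false_calls <- sum(!used)
  list(
    recall = mean(matched),
    n_true = nrow(truth),
    n_called = nrow(master),
    false_calls = false_calls,
    false_calls_per_10kb = if (is.na(genome_bp)) NA_real_ else
      10000 * false_calls / genome_bp
  )
}
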