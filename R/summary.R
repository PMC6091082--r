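#' Condition-overlap analysis of TSS activity
#'
#' Reports, for each condition, how many TSSs are active there and how many
#' are specific to it (active in that condition and no other), plus the
#' all-four-condition intersection and the intersection of the three light
#' conditions (CT, HL, HT, i.e. darkness excluded), each with its share of
#' the grand total rounded to one decimal.
#'
#' Can run either on a TSS table with `active_<condition>` flags or, for
#' checking printed summary numbers, directly on precomputed counts.
#'
#' @param tss master TSS table with logical `active_<condition>` columns.
#' @param counts alternative input: list with `total` and any of
#'   `all_four`, `no_dark` (the CT/HL/HT intersection) and per-condition
#'   `specific` counts, used as-is.
#' @return list with `total`, `per_condition` (data.frame `condition`,
#'   `active`, `specific`, `specific_percent`), `all_four` and `no_dark`
#'   (each `count` + `percent` of the grand total).
#' @export
activity_set_analysis <- function(tss = NULL, counts = NULL) {
  pct <- function(k, total) round(100 * k / total, 1)
  if (!is.null(counts)) {
    total <- counts$total
    out <- list(total = total)
    if (!is.null(counts$all_four)) {
      out$all_four <- list(count = counts$all_four,
                           percent = pct(counts$all_four, total))
    }
    if (!is.null(counts$no_dark)) {
      out$no_dark <- list(count = counts$no_dark,
                          percent = pct(counts$no_dark, total))
    }
    if (!is.null(counts$specific)) {
      out$per_condition <- data.frame(
        condition = names(counts$specific),
        specific = as.numeric(counts$specific),
        specific_percent = pct(as.numeric(counts$specific), total),
        stringsAsFactors = FALSE)
    }
    return(out)
  }
  if (is.null(tss) || nrow(tss) == 0L) stop("no TSS records given")
  act_cols <- paste0("active_", CONDITIONS)
  act_cols <- act_cols[act_cols %in% names(tss)]
  if (length(act_cols) == 0L) stop("tss table lacks active_<condition> columns")
  act <- as.matrix(tss[, act_cols, drop = FALSE])
  conds <- sub("^active_", "", act_cols)
  total <- nrow(tss)
  n_active_conds <- rowSums(act)
  per_condition <- data.frame(
    condition = conds,
    active = colSums(act),
    specific = vapply(seq_along(conds), function(j) {
      sum(act[, j] & n_active_conds == 1L)
    }, 0),
    stringsAsFactors = FALSE
  )
  per_condition$specific_percent <- pct(per_condition$specific, total)
  rownames(per_condition) <- NULL
  out <- list(total = total, per_condition = per_condition)
  if (all(CONDITIONS %in% conds)) {
    all_four <- sum(rowSums(act) == 4L)
    light <- paste0("active_", c("CT", "HL", "HT"))
    no_dark <- sum(rowSums(as.matrix(tss[, light])) == 3L)
    out$all_four <- list(count = all_four, percent = pct(all_four, total))
    out$no_dark <- list(count = no_dark, percent = pct(no_dark, total))
  }
  out
}

#' Initiation-nucleotide usage per TSS class
#'
#' Tallies the strand-aware +1 base at each TSS per class and overall,
#' with percentages rounded to one decimal. Ambiguous bases (N) go to a
#' separate bin with a warning.
#'
#' @param tss master TSS table; needs either a `nucleotide` column or
#'   `replicon`/`position`/`strand` plus `genome`.
#' @param genome optional named character vector of replicon sequences.
#' @return data.frame `tss_class` (including `"all"`), `base`, `count`,
#'   `percent`.
#' @export
nucleotide_usage <- function(tss, genome = NULL) {
  if (is.null(tss$nucleotide)) {
    if (is.null(genome)) stop("need a nucleotide column or a genome")
    tss$nucleotide <- genome_base(genome, tss$replicon, tss$position,
                                  tss$strand)
  }
  bases <- c("A", "C", "G", "T")
  if (any(!tss$nucleotide %in% bases)) {
    warning("ambiguous initiation base(s) counted in the 'N' bin")
  }
  tss$nucleotide[!tss$nucleotide %in% bases] <- "N"
  levels <- c(bases, if (any(tss$nucleotide == "N")) "N")
  tally <- function(x, label) {
    counts <- table(factor(x, levels = levels))
    data.frame(tss_class = label, base = levels,
               count = as.integer(counts),
               percent = round(100 * as.integer(counts) / length(x), 1),
               stringsAsFactors = FALSE)
  }
  out <- tally(tss$nucleotide, "all")
  for (cl in intersect(TSS_CLASSES, unique(tss$tss_class))) {
    out <- rbind(out, tally(tss$nucleotide[tss$tss_class == cl], cl))
  }
  rownames(out) <- NULL
  out
}

#' Ranked transcript-abundance table
#'
#' Sorts TSSs (rRNA-initiating ones excluded) by their maximal
#' per-condition mean normalized primary count, records under which
#' condition the maximum is reached, and attaches the contrast log2 fold
#' changes when differential results are supplied. Ties keep a stable
#' order by `tss_id`.
#'
#' @param tss classified master TSS table with library count columns.
#' @param size_factors from [compute_size_factors] (named by library).
#' @param annotation a [genome_annotation] (rRNA exclusion, product text).
#' @param det_results optional data.frame from [call_det].
#' @param top_n number of rows to keep (default 20; `Inf` for all).
#' @param aggregate per-condition summary of the normalized replicate
#'   counts: `"mean"` (default) or `"max"`.
#' @return data.frame ranked by descending abundance.
#' @export
rank_transcripts <- function(tss, size_factors, annotation,
                             det_results = NULL, top_n = 20,
                             aggregate = c("mean", "max")) {
  aggregate <- match.arg(aggregate)
  genes <- annotation$genes
  ft <- genes$feature_type[match(tss$gene_id, genes$gene_id)]
  rrna <- !is.na(ft) & ft == "rRNA" & tss$tss_class != "aTSS"
  tss <- tss[!rrna, , drop = FALSE]
  lib_cols <- intersect(names(size_factors), names(tss))
  if (length(lib_cols) == 0L) stop("no library columns matching size factors")
  norm <- sweep(as.matrix(tss[, lib_cols, drop = FALSE]), 2L,
                size_factors[lib_cols], "/")
  conds <- unique(cond_of_column(lib_cols))
  cond_mean <- vapply(conds, function(cd) {
    cols <- which(cond_of_column(lib_cols) == cd)
    if (aggregate == "mean") {
      rowMeans(norm[, cols, drop = FALSE])
    } else {
      apply(norm[, cols, drop = FALSE], 1L, max)
    }
  }, numeric(nrow(tss)))
  cond_mean <- matrix(cond_mean, ncol = length(conds),
                      dimnames = list(NULL, conds))
  peak <- apply(cond_mean, 1L, max)
  max_condition <- conds[apply(cond_mean, 1L, which.max)]
  out <- data.frame(
    tss_id = tss$tss_id,
    tss_class = tss$tss_class,
    replicon = tss$replicon,
    position = tss$position,
    strand = tss$strand,
    gene_id = tss$gene_id,
    product = genes$product[match(tss$gene_id, genes$gene_id)],
    peak_normalized_count = peak,
    max_condition = max_condition,
    stringsAsFactors = FALSE
  )
  if (!is.null(det_results)) {
    for (ct in unique(det_results$contrast)) {
      sub <- det_results[det_results$contrast == ct, ]
      out[[paste0("log2fc_", gsub("/", "_vs_", ct))]] <-
        sub$log2fc[match(out$tss_id, sub$tss_id)]
    }
  }
  out <- out[order(-out$peak_normalized_count, out$tss_id), , drop = FALSE]
  rownames(out) <- NULL
  head(out, n = if (is.finite(top_n)) top_n else nrow(out))
}

#' Antisense/target inverse-regulation query
#'
#' Convenience join: aTSSs whose host gene has a gTSS, where the two show
#' significant fold changes of opposite sign in the same contrast.
#'
#' @param tss classified master TSS table.
#' @param det_results data.frame from [call_det].
#' @return data.frame of candidate inverse-regulation pairs.
#' @export
inverse_regulation_pairs <- function(tss, det_results) {
  a <- tss[tss$tss_class == "aTSS" & !is.na(tss$gene_id), ]
  g <- tss[tss$tss_class == "gTSS" & !is.na(tss$gene_id), ]
  out <- list()
  for (ct in unique(det_results$contrast)) {
    res <- det_results[det_results$contrast == ct & det_results$is_det, ]
    ai <- merge(a[, c("tss_id", "gene_id")], res, by = "tss_id")
    gi <- merge(g[, c("tss_id", "gene_id")], res, by = "tss_id")
    pair <- merge(ai, gi, by = "gene_id", suffixes = c("_asRNA", "_mRNA"))
    pair <- pair[sign(pair$log2fc_asRNA) * sign(pair$log2fc_mRNA) < 0, ]
    if (nrow(pair)) out[[ct]] <- pair
  }
  if (length(out) == 0L) {
    return(data.frame(gene_id = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
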