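#' Parameters for positional TSS classification
#'
#' @param upstream_window maximal distance (nt) between a TSS and a
#'   downstream protein-coding gene start for the TSS to count as that
#'   gene's gTSS. Default 200.
#' @param antisense_flank how far (nt) beyond either gene end a TSS on the
#'   opposite strand still counts as antisense. Default 50.
#' @return A list of class `classification_params`.
#' @export
classification_params <- function(upstream_window = 200L, antisense_flank = 50L) {
  stopifnot(upstream_window > 0L, antisense_flank > 0L)
  structure(list(upstream_window = as.integer(upstream_window),
                 antisense_flank = as.integer(antisense_flank)),
            class = "classification_params")
}

#' Classify TSS positions against a genome annotation
#'
#' Assigns each TSS exactly one positional class, evaluated in precedence
#' order gTSS > iTSS > aTSS > nTSS:
#' \describe{
#'   \item{gTSS}{same strand, at or within `upstream_window` nt upstream of
#'     a protein-coding (CDS) gene start (distance 0..window). A TSS inside
#'     gene A that is also within the window upstream of gene B is the gTSS
#'     of B.}
#'   \item{iTSS}{inside a CDS on the same strand.}
#'   \item{aTSS}{inside, or within `antisense_flank` nt of either end of,
#'     any annotated gene on the opposite strand.}
#'   \item{nTSS}{everything else: intergenic TSSs and TSSs in front of
#'     non-coding features (ncRNA, rRNA, tRNA), whose gene id is recorded
#'     when the feature start lies within `upstream_window` nt downstream.}
#' }
#' Distances are strand-aware: upstream of a minus-strand gene means beyond
#' its annotated `end` coordinate. Ties for gTSS go to the nearest start.
#'
#' @param replicon,position,strand vectors describing the TSS positions
#'   (1-based; recycled to a common length).
#' @param annotation a [genome_annotation].
#' @param params a [classification_params].
#' @return data.frame with columns `tss_class`, `gene_id` (NA when no gene
#'   is associated) and `utr_length` (gTSS only, NA otherwise).
#' @export
classify_tss <- function(replicon, position, strand, annotation,
                         params = classification_params()) {
  n <- max(length(replicon), length(position), length(strand))
  replicon <- rep_len(as.character(replicon), n)
  position <- rep_len(as.integer(position), n)
  strand <- rep_len(as.character(strand), n)
  if (!all(strand %in% c("+", "-"))) stop("TSS strand must be '+' or '-'")
  lens <- annotation$replicons[replicon]
  if (anyNA(lens)) stop("unknown replicon in TSS positions")
  if (any(position < 1L | position > lens)) {
    stop("TSS position outside replicon bounds")
  }

  genes <- annotation$genes
  win <- params$upstream_window
  flank <- params$antisense_flank

  g_dist <- rep(NA_integer_, n)   # best (smallest) gTSS distance so far
  g_gene <- rep(NA_character_, n)
  i_gene <- rep(NA_character_, n)
  a_dist <- rep(NA_integer_, n)   # distance into/past the antisense gene
  a_gene <- rep(NA_character_, n)
  n_dist <- rep(NA_integer_, n)   # nearest downstream non-coding feature
  n_gene <- rep(NA_character_, n)

  for (k in seq_len(nrow(genes))) {
    g <- genes[k, ]
    on_rep <- replicon == g$replicon
    same <- on_rep & strand == g$strand
    # strand-aware signed distance from TSS to the annotated gene start:
    # positive while the TSS is upstream, 0 at the start base
    d <- if (g$strand == "+") g$start - position else position - g$end
    if (g$feature_type == "CDS") {
      hit <- same & d >= 0L & d <= win
      upd <- hit & (is.na(g_dist) | d < g_dist)
      g_dist[upd] <- d[upd]
      g_gene[upd] <- g$gene_id
      inside <- same & position >= g$start & position <= g$end
      i_gene[inside & is.na(i_gene)] <- g$gene_id
    } else {
      inside <- same & position >= g$start & position <= g$end
      hit <- (same & d >= 0L & d <= win) | inside
      dd <- ifelse(inside, 0L, d)
      upd <- hit & (is.na(n_dist) | dd < n_dist)
      n_dist[upd] <- dd[upd]
      n_gene[upd] <- g$gene_id
    }
    anti <- on_rep & strand != g$strand &
      position >= g$start - flank & position <= g$end + flank
    # prefer the gene whose body the TSS overlaps; then the nearest one
    gap <- pmax(g$start - position, position - g$end, 0L)
    upd <- anti & (is.na(a_dist) | gap < a_dist)
    a_dist[upd] <- gap[upd]
    a_gene[upd] <- g$gene_id
  }

  tss_class <- rep("nTSS", n)
  gene_id <- n_gene
  utr_length <- rep(NA_integer_, n)

  is_a <- !is.na(a_gene)
  tss_class[is_a] <- "aTSS"; gene_id[is_a] <- a_gene[is_a]
  is_i <- !is.na(i_gene)
  tss_class[is_i] <- "iTSS"; gene_id[is_i] <- i_gene[is_i]
  is_g <- !is.na(g_gene)
  tss_class[is_g] <- "gTSS"; gene_id[is_g] <- g_gene[is_g]
  utr_length[is_g] <- g_dist[is_g]

  data.frame(tss_class = tss_class, gene_id = gene_id,
             utr_length = utr_length, stringsAsFactors = FALSE)
}

#' Class counts and percentages
#'
#' Tallies TSS classes and reports each class's share of the total,
#' rounded to one decimal.
#'
#' @param x either a data.frame of classified TSS records (column
#'   `tss_class`) or a named numeric vector of class counts.
#' @return data.frame with columns `tss_class`, `count`, `percent`;
#'   attribute `total` holds the grand total.
#' @export
summarize_classes <- function(x) {
  if (is.data.frame(x)) {
    if (nrow(x) == 0L) stop("no classified TSS records")
    counts <- table(factor(x$tss_class, levels = TSS_CLASSES))
    counts <- setNames(as.numeric(counts), names(counts))
  } else {
    if (length(x) == 0L) stop("no class counts given")
    if (is.null(names(x)) || !all(names(x) %in% TSS_CLASSES)) {
      stop("count vector must be named with TSS classes")
    }
    counts <- setNames(as.numeric(x[TSS_CLASSES]), TSS_CLASSES)
    counts[is.na(counts)] <- 0
  }
  total <- sum(counts)
  if (total == 0) stop("no TSSs to summarize")
  out <- data.frame(
    tss_class = TSS_CLASSES,
    count = counts[TSS_CLASSES],
    percent = round(100 * counts[TSS_CLASSES] / total, 1),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "total") <- total
  out
}
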