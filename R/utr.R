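#' 5'-UTR length of a gTSS
#'
#' Strand-aware distance in nt from the TSS to the first base of the start
#' codon of its associated gene: `start - position` on the plus strand,
#' `position - end` on the minus strand. A TSS at the start codon has a
#' 5'-UTR of 0 nt (a leaderless-transcript candidate).
#'
#' @param tss data.frame of gTSS records with columns `position`, `strand`,
#'   `gene_id` (and optionally `tss_class`, which is then checked).
#' @param annotation a [genome_annotation].
#' @return Integer vector of UTR lengths, one per row of `tss`.
#' @export
compute_utr_length <- function(tss, annotation) {
  if (!is.null(tss$tss_class) && any(tss$tss_class != "gTSS")) {
    stop("compute_utr_length() applies to gTSSs only")
  }
  if (any(is.na(tss$gene_id))) stop("every gTSS needs an associated gene_id")
  genes <- annotation$genes
  idx <- match(tss$gene_id, genes$gene_id)
  if (anyNA(idx)) stop("unknown gene_id in gTSS records")
  utr <- ifelse(genes$strand[idx] == "+",
                genes$start[idx] - tss$position,
                tss$position - genes$end[idx])
  if (any(utr < 0)) stop("gTSS downstream of its gene start: negative UTR")
  as.integer(utr)
}

#' Median and histogram of 5'-UTR lengths
#'
#' The median for an even number of lengths is the lower of the two
#' central values (so the reported median is always an observed length).
#' Histogram bins are fixed 10-nt intervals `[0,10), [10,20), ...`.
#'
#' @param utr_lengths integer vector of 5'-UTR lengths (nt).
#' @return list with `median`, `n`, and `histogram` (data.frame
#'   `bin_start`, `bin_end`, `count`).
#' @export
utr_statistics <- function(utr_lengths) {
  if (length(utr_lengths) == 0L) stop("no UTR lengths given")
  if (any(utr_lengths < 0)) stop("UTR lengths cannot be negative")
  sorted <- sort(utr_lengths)
  med <- sorted[ceiling(length(sorted) / 2)]
  bin_start <- seq(0L, max(10L, 10L * (max(sorted) %/% 10L + 1L) - 10L), by = 10L)
  counts <- vapply(bin_start, function(b) {
    sum(sorted >= b & sorted < b + 10L)
  }, 0L)
  list(
    median = med,
    n = length(utr_lengths),
    histogram = data.frame(bin_start = bin_start, bin_end = bin_start + 10L,
                           count = counts)
  )
}

#' Leaderless-transcript / start-codon re-annotation decision
#'
#' Applies the homolog-evidence rule for gTSSs close to their start codon:
#' only TSSs strictly less than 10 nt from the start codon are evaluated
#' (`normal` otherwise). Among those, strictly more than 45% of homologs
#' sharing the annotated start supports a leaderless transcript; strictly
#' more than 45% supporting a shorter protein proposes re-annotating the
#' start codon. Both fractions exceeding 45% is reported as `ambiguous`,
#' neither as `no_evidence`. The homolog fractions come from an external
#' protein-homology search and are consumed as a precomputed table.
#'
#' @param tss_to_start_distance distance (nt) from TSS to start codon.
#' @param fraction_matching_start fraction of homologs whose start matches
#'   the annotated start.
#' @param fraction_supporting_shorter fraction of homologs supporting a
#'   shorter protein.
#' @param distance_threshold strict upper bound on the distance (default 10).
#' @param fraction_threshold strict lower bound on the fractions (default 0.45).
#' @return Character vector over `{normal, leaderless, reannotate,
#'   ambiguous, no_evidence}` (vectorized over the inputs).
#' @export
decide_start_codon_status <- function(tss_to_start_distance,
                                      fraction_matching_start,
                                      fraction_supporting_shorter,
                                      distance_threshold = 10,
                                      fraction_threshold = 0.45) {
  n <- max(length(tss_to_start_distance), length(fraction_matching_start),
           length(fraction_supporting_shorter))
  d <- rep_len(tss_to_start_distance, n)
  fm <- rep_len(fraction_matching_start, n)
  fs <- rep_len(fraction_supporting_shorter, n)
  if (any(d < 0)) stop("distance to start codon cannot be negative")
  if (any(fm < 0 | fm > 1 | fs < 0 | fs > 1, na.rm = TRUE)) {
    stop("homolog fractions must lie in [0, 1]")
  }
  status <- rep("normal", n)
  near <- d < distance_threshold
  lead <- near & !is.na(fm) & fm > fraction_threshold
  rean <- near & !is.na(fs) & fs > fraction_threshold
  status[near] <- "no_evidence"
  status[lead & !rean] <- "leaderless"
  status[rean & !lead] <- "reannotate"
  status[lead & rean] <- "ambiguous"
  status
}

#' Annotate 5'-UTRs and start-codon status for a classified TSS table
#'
#' Computes UTR lengths for all gTSSs and, where homolog evidence is
#' supplied, the leaderless / re-annotation decision for gTSSs within 10 nt
#' of the start codon.
#'
#' @param tss classified master TSS table (columns `tss_class`, `gene_id`,
#'   `position`, `strand`).
#' @param annotation a [genome_annotation].
#' @param homolog_evidence optional data.frame `orf_id`,
#'   `fraction_matching_start`, `fraction_supporting_shorter` keyed by the
#'   gene id of the ORF.
#' @return `tss` with `utr_length` filled for gTSSs and a
#'   `start_codon_status` column.
#' @export
annotate_utrs <- function(tss, annotation, homolog_evidence = NULL) {
  tss$utr_length <- NA_integer_
  is_g <- tss$tss_class == "gTSS"
  if (any(is_g)) {
    tss$utr_length[is_g] <- compute_utr_length(tss[is_g, , drop = FALSE],
                                               annotation)
  }
  fm <- rep(NA_real_, nrow(tss))
  fs <- rep(NA_real_, nrow(tss))
  if (!is.null(homolog_evidence)) {
    idx <- match(tss$gene_id, homolog_evidence$orf_id)
    fm <- homolog_evidence$fraction_matching_start[idx]
    fs <- homolog_evidence$fraction_supporting_shorter[idx]
  }
  tss$start_codon_status <- NA_character_
  tss$start_codon_status[is_g] <- decide_start_codon_status(
    tss$utr_length[is_g], fm[is_g], fs[is_g])
  tss
}
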