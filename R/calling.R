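#' Parameters for replicate-aware TSS calling
#'
#' A genomic position is called as a TSS candidate in a condition when its
#' primary (TEX-treated) 5'-end count reaches
#' `min_primary_count_per_replicate` in every replicate and the
#' pseudocounted primary-over-minus enrichment ratio reaches
#' `min_enrichment`; candidate runs closer than `cluster_window` bp
#' collapse to their strongest position. A master-table TSS is "active" in
#' a condition when its summed raw primary count there reaches
#' `min_raw_reads_activity` (default 300 reads).
#'
#' @param pseudocount added to both numerator and denominator read sums.
#' @param min_enrichment minimal primary/minus enrichment ratio.
#' @param min_primary_count_per_replicate per-replicate floor on the
#'   primary count.
#' @param cluster_window bp; called positions closer than this on the same
#'   strand are clustered.
#' @param min_raw_reads_activity per-condition activity threshold on the
#'   summed raw primary counts.
#' @return A list of class `calling_params`.
#' @export
calling_params <- function(pseudocount = 1L,
                           min_enrichment = 2.0,
                           min_primary_count_per_replicate = 10L,
                           cluster_window = 3L,
                           min_raw_reads_activity = 300L) {
  stopifnot(pseudocount >= 1, min_enrichment > 1, cluster_window >= 0,
            min_raw_reads_activity >= 1)
  structure(list(
    pseudocount = pseudocount,
    min_enrichment = min_enrichment,
    min_primary_count_per_replicate = min_primary_count_per_replicate,
    cluster_window = as.integer(cluster_window),
    min_raw_reads_activity = min_raw_reads_activity
  ), class = "calling_params")
}

#' Pseudocounted primary-over-minus enrichment ratio
#'
#' `(sum(primary) + pseudocount) / (sum(minus) + pseudocount)`, summing
#' over replicates; symmetric in replicate order.
#'
#' @param primary_counts,minus_counts per-replicate raw counts at one
#'   position (equal length).
#' @param params a [calling_params].
#' @return The enrichment ratio.
#' @export
compute_enrichment <- function(primary_counts, minus_counts,
                               params = calling_params()) {
  if (length(primary_counts) != length(minus_counts)) {
    stop("primary and minus libraries have different replicate counts")
  }
  (sum(primary_counts) + params$pseudocount) /
    (sum(minus_counts) + params$pseudocount)
}

condition_tracks <- function(tracks, condition, type) {
  sel <- Filter(function(t) t$condition == condition && t$type == type, tracks)
  sel[order(vapply(sel, function(t) t$replicate, 0L))]
}

#' Call TSS candidates for one condition
#'
#' Applies the replicate-consistency and enrichment criteria position-wise,
#' then collapses runs of called positions closer than the cluster window
#' on the same strand to the position with the largest summed primary
#' count (ties go to the most upstream position relative to the strand).
#'
#' @param tracks named list of [five_prime_track] objects containing this
#'   condition's primary and minus replicate tracks.
#' @param condition the condition to call.
#' @param params a [calling_params].
#' @return data.frame of candidates: `replicon`, `position`, `strand`,
#'   `condition`, `primary_sum`, `minus_sum`, `enrichment`.
#' @export
call_condition_tss <- function(tracks, condition, params = calling_params()) {
  primary <- condition_tracks(tracks, condition, "primary")
  minus <- condition_tracks(tracks, condition, "minus")
  if (length(primary) == 0L) stop("no primary tracks for condition ", condition)
  if (length(minus) != length(primary)) {
    stop("missing minus replicate track(s) for condition ", condition)
  }
  replicons <- names(primary[[1]]$counts)
  out <- list()
  for (rep_name in replicons) {
    for (s in c("+", "-")) {
      P <- vapply(primary, function(t) t$counts[[rep_name]][[s]],
                  primary[[1]]$counts[[rep_name]][[s]])
      M <- vapply(minus, function(t) t$counts[[rep_name]][[s]],
                  minus[[1]]$counts[[rep_name]][[s]])
      P <- matrix(P, ncol = length(primary))
      M <- matrix(M, ncol = length(minus))
      psum <- rowSums(P)
      msum <- rowSums(M)
      pmin_rep <- do.call(pmin, as.data.frame(P))
      enr <- (psum + params$pseudocount) / (msum + params$pseudocount)
      called <- which(pmin_rep >= params$min_primary_count_per_replicate &
                        enr >= params$min_enrichment)
      if (length(called) == 0L) next
      keep <- cluster_called_positions(called, psum[called], s,
                                       params$cluster_window)
      out[[length(out) + 1L]] <- data.frame(
        replicon = rep_name, position = keep, strand = s,
        condition = condition,
        primary_sum = psum[keep], minus_sum = msum[keep],
        enrichment = enr[keep], stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0L) {
    return(data.frame(replicon = character(), position = integer(),
                      strand = character(), condition = character(),
                      primary_sum = numeric(), minus_sum = numeric(),
                      enrichment = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$replicon, res$position, res$strand), , drop = FALSE]
}

# collapse runs of called positions closer than window bp; keep the
# position with maximal summed primary count, ties to the most upstream
# position relative to the strand
cluster_called_positions <- function(positions, weights, strand, window) {
  if (window <= 0L || length(positions) <= 1L) return(positions)
  o <- order(positions)
  positions <- positions[o]; weights <- weights[o]
  grp <- cumsum(c(1L, as.integer(diff(positions) >= window)))
  keep <- integer(0)
  for (g in unique(grp)) {
    idx <- which(grp == g)
    best <- idx[weights[idx] == max(weights[idx])]
    pick <- if (strand == "+") best[1L] else best[length(best)]
    keep <- c(keep, positions[pick])
  }
  keep
}

#' Build the master TSS table across conditions
#'
#' Takes the union of the per-condition candidate positions, attaches raw
#' primary counts from every library, flags per-condition activity
#' (summed raw primary counts >= `min_raw_reads_activity`), and drops TSSs
#' active in no condition.
#'
#' @param candidates list of per-condition candidate data.frames from
#'   [call_condition_tss] (or one combined data.frame).
#' @param tracks named list of all [five_prime_track] objects.
#' @param params a [calling_params].
#' @param genome optional genome (named character vector); when given, the
#'   strand-aware initiation nucleotide is recorded per TSS.
#' @return data.frame with one row per master TSS: `tss_id`, `replicon`,
#'   `position`, `strand`, `nucleotide` (if genome given), one raw-count
#'   column per primary library (`<cond>_<rep>`), logical `active_<cond>`
#'   flags and the comma-separated `active_conditions` string.
#' @export
build_master_table <- function(candidates, tracks, params = calling_params(),
                               genome = NULL) {
  if (is.data.frame(candidates)) candidates <- list(candidates)
  all_cand <- do.call(rbind, candidates)
  if (is.null(all_cand) || nrow(all_cand) == 0L) {
    stop("no TSS candidates in any condition")
  }
  key <- unique(all_cand[, c("replicon", "position", "strand")])
  key <- key[order(key$replicon, key$position, key$strand), , drop = FALSE]
  rownames(key) <- NULL
  master <- key
  master$tss_id <- sprintf("TSS_%05d", seq_len(nrow(master)))
  master <- master[, c("tss_id", "replicon", "position", "strand")]
  if (!is.null(genome)) {
    master$nucleotide <- genome_base(genome, master$replicon,
                                     master$position, master$strand)
  }
  primary <- Filter(function(t) t$type == "primary", tracks)
  conds <- sort(unique(vapply(primary, function(t) t$condition, "")),
                method = "radix")
  conds <- CONDITIONS[CONDITIONS %in% conds]
  for (t in primary) {
    col <- sprintf("%s_%d", t$condition, t$replicate)
    master[[col]] <- track_counts(t, master$replicon, master$strand,
                                  master$position)
  }
  for (cond in conds) {
    cols <- grep(sprintf("^%s_\\d+$", cond), names(master), value = TRUE)
    cond_sum <- rowSums(master[, cols, drop = FALSE])
    master[[paste0("active_", cond)]] <-
      cond_sum >= params$min_raw_reads_activity
  }
  act_cols <- paste0("active_", conds)
  act <- as.matrix(master[, act_cols, drop = FALSE])
  master$active_conditions <- apply(act, 1L, function(a) {
    paste(conds[a], collapse = ",")
  })
  master <- master[rowSums(act) > 0L, , drop = FALSE]
  rownames(master) <- NULL
  master
}
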