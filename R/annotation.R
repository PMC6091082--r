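#' Genome annotation container
#'
#' Holds stranded gene-level features (CDS, rRNA, tRNA, ncRNA) on named
#' replicons together with replicon lengths. Coordinates are 1-based and
#' inclusive throughout the package, matching GFF3.
#'
#' @param genes data.frame with columns `gene_id`, `replicon`, `start`,
#'   `end`, `strand` (`"+"` or `"-"`), `feature_type` (one of `"CDS"`,
#'   `"rRNA"`, `"tRNA"`, `"ncRNA"`) and optionally `product`.
#' @param replicons named numeric vector of replicon lengths in bp.
#' @return An object of class `genome_annotation`.
#' @export
genome_annotation <- function(genes, replicons) {
  required <- c("gene_id", "replicon", "start", "end", "strand", "feature_type")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols) > 0L) {
    stop("annotation is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(names(replicons)) || any(!nzchar(names(replicons)))) {
    stop("replicon lengths must be a named vector")
  }
  if (!("product" %in% names(genes))) genes$product <- NA_character_
  genes <- genes[, c(required, "product")]
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  if (anyDuplicated(genes$gene_id)) stop("gene_id values must be unique")
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("gene strand must be '+' or '-' (unstranded features cannot be classified)")
  }
  if (!all(genes$feature_type %in% c("CDS", "rRNA", "tRNA", "ncRNA"))) {
    stop("feature_type must be one of CDS, rRNA, tRNA, ncRNA")
  }
  if (!all(genes$replicon %in% names(replicons))) {
    stop("gene replicon not present in replicon length table")
  }
  len <- replicons[genes$replicon]
  if (any(genes$start < 1L) || any(genes$end < genes$start) || any(genes$end > len)) {
    stop("gene coordinates must satisfy 1 <= start <= end <= replicon length")
  }
  rownames(genes) <- NULL
  structure(list(genes = genes, replicons = replicons),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", length(x$replicons), "replicon(s),",
      nrow(x$genes), "gene features\n")
  tab <- table(x$genes$feature_type)
  cat(" ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# strand-aware annotated start coordinate of each gene (TSS-side end)
gene_start_coord <- function(genes) {
  ifelse(genes$strand == "+", genes$start, genes$end)
}

#' Strand-aware genome base lookup
#'
#' Returns the base a transcript starting at `position` on `strand` would
#' begin with: the genome base itself on the plus strand, its complement on
#' the minus strand.
#'
#' @param genome named character vector of replicon sequences.
#' @param replicon,position,strand vectors describing positions (recycled).
#' @return Character vector of bases (`A`, `C`, `G`, `T`, or `N`).
#' @export
genome_base <- function(genome, replicon, position, strand) {
  n <- max(length(replicon), length(position), length(strand))
  replicon <- rep_len(replicon, n)
  position <- rep_len(as.integer(position), n)
  strand <- rep_len(strand, n)
  base <- character(n)
  for (rep_name in unique(replicon)) {
    idx <- which(replicon == rep_name)
    seq <- genome[[rep_name]]
    if (is.null(seq)) stop("unknown replicon: ", rep_name)
    base[idx] <- substring(seq, position[idx], position[idx])
  }
  base <- toupper(base)
  neg <- strand == "-"
  base[neg] <- chartr("ACGT", "TGCA", base[neg])
  base
}
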