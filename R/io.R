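#' @importFrom stats median rnbinom rpois runif setNames p.adjust pnorm lm coef quantile var rlnorm
#' @importFrom utils read.delim write.table head
NULL

#' Growth-condition labels used throughout the package
#'
#' `CT`, `DK`, `HL`, `HT`: control, dark, high light, high temperature.
#' @export
CONDITIONS <- c("CT", "DK", "HL", "HT")

TSS_CLASSES <- c("gTSS", "iTSS", "aTSS", "nTSS")

# canonical library name, also the bedGraph filename stem
library_name <- function(type, condition, replicate) {
  sprintf("%s_%s_%s", condition, replicate, type)
}

#' Per-position 5'-end count track for one sequencing library
#'
#' Stores, for one library (TEX-treated `primary` or untreated `minus`
#' control; one condition; one replicate), the number of read 5' ends at
#' every genomic position, per replicon and strand. Positions are 1-based.
#'
#' @param counts list: replicon name -> list of integer vectors `"+"` and
#'   `"-"`, each of length equal to the replicon.
#' @param type `"primary"` or `"minus"`.
#' @param condition one of `CT`, `DK`, `HL`, `HT`.
#' @param replicate replicate number (integer).
#' @return An object of class `five_prime_track`.
#' @export
five_prime_track <- function(counts, type, condition, replicate) {
  type <- match.arg(type, c("primary", "minus"))
  condition <- match.arg(condition, CONDITIONS)
  for (rep_name in names(counts)) {
    for (s in c("+", "-")) {
      v <- counts[[rep_name]][[s]]
      if (is.null(v)) stop("missing ", s, " strand counts for ", rep_name)
      if (any(v < 0)) stop("counts must be non-negative")
      counts[[rep_name]][[s]] <- as.integer(v)
    }
  }
  structure(list(counts = counts, type = type, condition = condition,
                 replicate = as.integer(replicate)),
            class = "five_prime_track")
}

#' @export
print.five_prime_track <- function(x, ...) {
  total <- sum(vapply(x$counts, function(r) sum(r[["+"]]) + sum(r[["-"]]), 0))
  cat(sprintf("five_prime_track %s: %d replicon(s), %.0f read 5' ends\n",
              library_name(x$type, x$condition, x$replicate),
              length(x$counts), total))
  invisible(x)
}

track_counts <- function(track, replicon, strand, positions) {
  out <- integer(length(positions))
  for (rep_name in unique(replicon)) {
    for (s in c("+", "-")) {
      idx <- which(replicon == rep_name & strand == s)
      if (length(idx)) out[idx] <- track$counts[[rep_name]][[s]][positions[idx]]
    }
  }
  out
}

#' Read a genome FASTA file
#'
#' @param path FASTA file.
#' @return Named character vector of uppercase replicon sequences.
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(seqs))
  # keep only the first whitespace-delimited token of each header
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' Write a genome FASTA file
#'
#' @param genome named character vector of replicon sequences.
#' @param path output file.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path, width = 70L)
  invisible(path)
}

#' Read a GFF3 gene annotation
#'
#' Loads gene-level features (CDS, rRNA, tRNA, ncRNA) with strand and type.
#' Coordinates stay 1-based inclusive as in GFF3. Replicon lengths are taken
#' from `##sequence-region` pragmas when present, otherwise from the maximal
#' feature end per replicon.
#'
#' @param path GFF3 file.
#' @return A [genome_annotation].
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9L) {
      stop("malformed GFF3 line ", i, ": expected 9 tab-separated fields")
    }
    if (is.na(suppressWarnings(as.integer(f[4]))) ||
        is.na(suppressWarnings(as.integer(f[5])))) {
      stop("malformed GFF3 line ", i, ": non-numeric coordinates")
    }
    if (as.integer(f[5]) < as.integer(f[4])) {
      stop("invalid GFF3 line ", i, ": end < start")
    }
  }
  gr <- rtracklayer::import(path, format = "gff3")
  keep <- as.character(gr$type) %in% c("CDS", "rRNA", "tRNA", "ncRNA")
  gr <- gr[keep]
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(!strand %in% c("+", "-"))) {
    stop("feature without strand ('.') cannot be used: strand is required ",
         "for TSS classification")
  }
  ids <- gr$ID
  if (is.null(ids) || anyNA(ids)) stop("all features need an ID attribute")
  product <- if (!is.null(gr$product)) as.character(gr$product) else NA_character_
  genes <- data.frame(
    gene_id = as.character(ids),
    replicon = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = strand,
    feature_type = as.character(gr$type),
    product = product,
    stringsAsFactors = FALSE
  )
  pragma <- grep("^##sequence-region", lines, value = TRUE)
  if (length(pragma)) {
    parts <- strsplit(trimws(pragma), "\\s+")
    replicons <- setNames(
      vapply(parts, function(p) as.numeric(p[4]), 0),
      vapply(parts, function(p) p[2], "")
    )
  } else {
    replicons <- tapply(genes$end, genes$replicon, max)
    replicons <- setNames(as.numeric(replicons), names(replicons))
  }
  genome_annotation(genes, replicons)
}

#' Write a genome annotation as GFF3
#'
#' @param annotation a [genome_annotation].
#' @param path output file.
#' @export
write_gff3 <- function(annotation, path) {
  genes <- annotation$genes
  genes <- genes[order(genes$replicon, genes$start, genes$end, genes$strand), ]
  gr <- GenomicRanges::GRanges(
    seqnames = genes$replicon,
    ranges = IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand,
    type = genes$feature_type,
    source = "drnatss",
    phase = ifelse(genes$feature_type == "CDS", 0L, NA_integer_),
    ID = genes$gene_id,
    product = genes$product
  )
  GenomeInfoDb_seqlengths(gr) <- annotation$replicons[
    GenomeInfoDb::seqlevels(gr)]
  rtracklayer::export(gr, path, format = "gff3")
  rewrite_gff3_header(path, annotation$replicons)
  invisible(path)
}

# setter indirection for the GenomeInfoDb replacement generic
`GenomeInfoDb_seqlengths<-` <- function(x, value) {
  GenomeInfoDb::seqlengths(x) <- value
  x
}

# reproducible GFF3 header: drop the volatile ##date/##source-version lines
# and state replicon bounds as ##sequence-region pragmas
rewrite_gff3_header <- function(path, replicons) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "##date") &
                   !startsWith(lines, "##source-version")]
  if (!is.null(replicons)) {
    pragma <- sprintf("##sequence-region %s 1 %d",
                      names(replicons), as.integer(replicons))
    lines <- append(lines, pragma, after = 1L)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read one library's strand-specific bedGraph pair
#'
#' bedGraph intervals are 0-based half-open; an interval `[s, e)` with value
#' `v` expands to 1-based positions `s+1 ... e`, each with count `v`.
#'
#' @param path_plus bedGraph of plus-strand 5'-end counts.
#' @param path_minus_strand bedGraph of minus-strand 5'-end counts.
#' @param type,condition,replicate library key (see [five_prime_track]).
#' @param replicons named numeric vector of replicon lengths.
#' @return A [five_prime_track].
#' @export
read_bedgraph_pair <- function(path_plus, path_minus_strand,
                               type, condition, replicate, replicons) {
  counts <- lapply(replicons, function(L) {
    list("+" = integer(L), "-" = integer(L))
  })
  load_one <- function(path, strand) {
    gr <- rtracklayer::import(path, format = "bedGraph")
    if (length(gr) == 0L) return(invisible())
    if (any(gr$score < 0)) stop("negative count in ", path)
    if (any(gr$score != round(gr$score))) stop("non-integer count in ", path)
    by_rep <- split(gr, as.character(GenomicRanges::seqnames(gr)))
    for (rep_name in names(by_rep)) {
      if (!rep_name %in% names(replicons)) {
        stop("unknown replicon in ", path, ": ", rep_name)
      }
      g <- by_rep[[rep_name]]
      s <- GenomicRanges::start(g); e <- GenomicRanges::end(g)
      o <- order(s)
      if (any(s[o][-1] <= e[o][-length(e)])) {
        stop("overlapping intervals on the same strand in ", path)
      }
      if (any(e > replicons[[rep_name]])) {
        stop("interval beyond replicon end in ", path)
      }
      pos <- sequence(e - s + 1L, from = s)
      counts[[rep_name]][[strand]][pos] <<-
        as.integer(rep(g$score, e - s + 1L))
    }
  }
  load_one(path_plus, "+")
  load_one(path_minus_strand, "-")
  five_prime_track(counts, type, condition, replicate)
}

#' Write one library's strand-specific bedGraph pair
#'
#' Files are named `<condition>_<replicate>_<type>_<fwd|rev>.bedgraph`
#' (fwd = plus strand). Zero-count positions are omitted; runs of equal
#' counts are merged into single 0-based half-open intervals.
#'
#' @param track a [five_prime_track].
#' @param dir output directory.
#' @return Character vector of the two file paths.
#' @export
write_track_bedgraphs <- function(track, dir) {
  stem <- library_name(track$type, track$condition, track$replicate)
  paths <- c(
    "+" = file.path(dir, paste0(stem, "_fwd.bedgraph")),
    "-" = file.path(dir, paste0(stem, "_rev.bedgraph"))
  )
  for (s in c("+", "-")) {
    con <- file(paths[[s]], "w")
    for (rep_name in sort(names(track$counts))) {
      v <- track$counts[[rep_name]][[s]]
      r <- rle(v)
      ends <- cumsum(r$lengths)
      starts0 <- ends - r$lengths  # 0-based
      keep <- r$values > 0L
      if (any(keep)) {
        writeLines(sprintf("%s\t%d\t%d\t%d", rep_name,
                           starts0[keep], ends[keep], r$values[keep]), con)
      }
    }
    close(con)
  }
  paths
}

#' Read a library's 5'-end counts from an alignment file
#'
#' Convenience ingestion for mapped reads: takes each aligned read's
#' 5'-most base (leftmost aligned position on the plus strand, rightmost
#' on the minus strand) and tallies per-position counts into the same
#' track structure the bedGraph reader produces. Secondary and
#' supplementary alignments are skipped.
#'
#' @param path BAM file (indexed or not).
#' @param type,condition,replicate library key (see [five_prime_track]).
#' @param replicons named numeric vector of replicon lengths.
#' @return A [five_prime_track].
#' @export
read_bam_five_prime <- function(path, type, condition, replicate, replicons) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("BAM ingestion needs the Rsamtools package")
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flag, what = c("rname", "pos", "strand", "cigar"))
  aln <- Rsamtools::scanBam(path, param = param)[[1]]
  keep <- !is.na(aln$pos)
  rname <- as.character(aln$rname)[keep]
  strand <- as.character(aln$strand)[keep]
  pos <- aln$pos[keep]
  # reference span from the CIGAR, for the minus-strand 5' end
  span <- cigar_reference_span(aln$cigar[keep])
  five <- ifelse(strand == "+", pos, pos + span - 1L)
  counts <- lapply(replicons, function(L) {
    list("+" = integer(L), "-" = integer(L))
  })
  for (rep_name in unique(rname)) {
    for (s in c("+", "-")) {
      idx <- rname == rep_name & strand == s
      if (!any(idx)) next
      tab <- table(five[idx])
      at <- as.integer(names(tab))
      counts[[rep_name]][[s]][at] <- as.integer(tab)
    }
  }
  five_prime_track(counts, type, condition, replicate)
}

# reference-consuming CIGAR span (M/D/N/=/X operations)
cigar_reference_span <- function(cigar) {
  vapply(cigar, function(cg) {
    ops <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    sum(vapply(ops, function(o) {
      op <- substr(o, nchar(o), nchar(o))
      if (op %in% c("M", "D", "N", "=", "X")) {
        as.integer(substr(o, 1, nchar(o) - 1L))
      } else 0L
    }, 0L))
  }, 0L, USE.NAMES = FALSE)
}

#' Write the master TSS table
#'
#' Writes a TSV with one row per TSS (position, strand, class, initiation
#' nucleotide, per-library raw counts, per-contrast Log2FC and padj when
#' present), and optionally a companion GFF3 of single-base point features
#' using the type dialect `gene_TSS` / `internal_TSS` / `antisense_TSS` /
#' `ncRNA_TSS`.
#'
#' @param tss data.frame of TSS records.
#' @param path output TSV path.
#' @param gff3_path optional companion GFF3 path.
#' @param replicons named replicon lengths (needed for the GFF3 header).
#' @export
write_tss_table <- function(tss, path, gff3_path = NULL, replicons = NULL) {
  ord <- order(tss$replicon, tss$position, tss$strand)
  tss <- tss[ord, , drop = FALSE]
  write.table(tss, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(gff3_path)) {
    dialect <- c(gTSS = "gene_TSS", iTSS = "internal_TSS",
                 aTSS = "antisense_TSS", nTSS = "ncRNA_TSS")
    gr <- GenomicRanges::GRanges(
      seqnames = tss$replicon,
      ranges = IRanges::IRanges(tss$position, tss$position),
      strand = tss$strand,
      type = dialect[tss$tss_class],
      source = "drnatss",
      ID = tss$tss_id
    )
    if (!is.null(replicons)) {
      GenomeInfoDb_seqlengths(gr) <- replicons[GenomeInfoDb::seqlevels(gr)]
    }
    rtracklayer::export(gr, gff3_path, format = "gff3")
    rewrite_gff3_header(gff3_path, replicons)
  }
  invisible(path)
}

#' Read a TSS table written by [write_tss_table]
#'
#' @param path TSV path.
#' @return data.frame of TSS records.
#' @export
read_tss_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
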