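#' Assemble the per-TSS count matrix for differential testing
#'
#' Rows are TSSs, columns the primary libraries (`<condition>_<replicate>`).
#' TSSs initiating rRNAs or tRNAs (assigned gene of that feature type,
#' sense-side classes) are excluded, and only TSSs whose raw count reaches
#' `min_max_count` in at least one library are kept.
#'
#' @param master classified master TSS table (needs `tss_id`, `tss_class`,
#'   `gene_id` and the per-library count columns).
#' @param annotation a [genome_annotation] (for the rRNA/tRNA exclusion).
#' @param min_max_count row filter threshold (default 300 raw reads).
#' @return Integer matrix with TSS ids as row names.
#' @export
build_count_matrix <- function(master, annotation, min_max_count = 300) {
  lib_cols <- grep(sprintf("^(%s)_\\d+$", paste(CONDITIONS, collapse = "|")),
                   names(master), value = TRUE)
  if (length(lib_cols) == 0L) stop("master table has no library count columns")
  ft <- annotation$genes$feature_type[match(master$gene_id,
                                            annotation$genes$gene_id)]
  sense_ribo <- !is.na(ft) & ft %in% c("rRNA", "tRNA") &
    master$tss_class != "aTSS"
  keep <- !sense_ribo
  counts <- as.matrix(master[keep, lib_cols, drop = FALSE])
  rownames(counts) <- master$tss_id[keep]
  storage.mode(counts) <- "integer"
  counts[apply(counts, 1L, max) >= min_max_count, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' For each library, the size factor is the median over zero-free rows of
#' the ratio between that library's count and the row's geometric mean.
#'
#' @param counts count matrix (rows TSSs, columns libraries).
#' @return Named numeric vector of strictly positive size factors.
#' @export
compute_size_factors <- function(counts) {
  counts <- as.matrix(counts)
  zero_free <- rowSums(counts == 0) == 0L
  if (!any(zero_free)) {
    stop("no rows without zeros: median-of-ratios is undefined; add a ",
         "pseudocount to the matrix or relax the row filter")
  }
  logc <- log(counts[zero_free, , drop = FALSE])
  log_geo <- rowMeans(logc)
  sf <- apply(exp(logc - log_geo), 2L, median)
  if (any(!is.finite(sf) | sf <= 0)) stop("non-positive size factor")
  sf
}

cond_of_column <- function(cols) sub("_\\d+$", "", cols)

# dispersion trend alpha(mu) = max(c0 + c1/mu, floor), fitted by OLS on the
# per-TSS method-of-moments estimates; falls back to the mean when the fit
# is degenerate
fit_dispersion_trend <- function(base_mean, alpha_mm, floor = 1e-8) {
  ok <- is.finite(alpha_mm) & is.finite(base_mean) & base_mean > 0
  if (sum(ok) >= 10L && length(unique(round(base_mean[ok]))) > 2L) {
    fit <- try(lm(alpha_mm[ok] ~ I(1 / base_mean[ok])), silent = TRUE)
    if (!inherits(fit, "try-error") && all(is.finite(coef(fit)))) {
      cf <- coef(fit)
      return(function(mu) pmax(cf[[1]] + cf[[2]] / mu, floor))
    }
  }
  a0 <- mean(alpha_mm[ok])
  if (!is.finite(a0)) a0 <- floor
  function(mu) pmax(rep(a0, length(mu)), floor)
}

#' Negative-binomial Wald test for one condition contrast
#'
#' Counts are normalized by the size factors; per-TSS dispersion is
#' estimated by the method of moments within each condition, shrunk toward
#' a mean-dispersion trend fitted across all TSSs, and the log2 fold change
#' `log2((mean_trt + 0.5) / (mean_ctl + 0.5))` is tested with a Wald
#' statistic using the delta-method NB variance of the log ratio.
#'
#' @param counts count matrix from [build_count_matrix].
#' @param size_factors from [compute_size_factors].
#' @param contrast length-2 character vector `c(treatment, control)`,
#'   e.g. `c("DK", "CT")`.
#' @param trend_weight weight of the trend in the shrunk dispersion
#'   (0 = raw per-TSS estimate, 1 = pure trend). With two replicates per
#'   condition the genewise estimate has about one degree of freedom, so
#'   the default leans heavily on the trend.
#' @return data.frame `tss_id`, `contrast`, `base_mean`, `log2fc`,
#'   `p_value`.
#' @export
nb_contrast_test <- function(counts, size_factors, contrast,
                             trend_weight = 0.9) {
  stopifnot(length(contrast) == 2L)
  conds <- cond_of_column(colnames(counts))
  trt_cols <- which(conds == contrast[1])
  ctl_cols <- which(conds == contrast[2])
  if (length(trt_cols) < 2L || length(ctl_cols) < 2L) {
    stop("need >= 2 replicates per condition to estimate dispersion")
  }
  norm <- sweep(as.matrix(counts), 2L, size_factors, "/")
  inv_s <- 1 / size_factors

  group_stats <- function(cols) {
    m <- rowMeans(norm[, cols, drop = FALSE])
    v <- apply(norm[, cols, drop = FALSE], 1L, var)
    # MoM: Var(K_j/s_j) = mu/s_j + alpha mu^2, averaged over the group
    shot <- m * mean(inv_s[cols])
    alpha <- (v - shot) / m^2
    list(mean = m, alpha = alpha, n = length(cols),
         mean_inv_s = mean(inv_s[cols]))
  }
  trt <- group_stats(trt_cols)
  ctl <- group_stats(ctl_cols)
  base_mean <- rowMeans(norm[, c(trt_cols, ctl_cols), drop = FALSE])
  alpha_mm <- rowMeans(cbind(trt$alpha, ctl$alpha))
  trend <- fit_dispersion_trend(base_mean, alpha_mm)
  alpha_raw <- ifelse(is.finite(alpha_mm), alpha_mm, 0)
  alpha <- pmax(trend_weight * trend(base_mean) +
                  (1 - trend_weight) * alpha_raw, 1e-8)

  mu_t <- trt$mean + 0.5
  mu_c <- ctl$mean + 0.5
  log2fc <- log2(mu_t / mu_c)
  var_log <- (trt$mean_inv_s / mu_t + alpha) / trt$n +
    (ctl$mean_inv_s / mu_c + alpha) / ctl$n
  se_log2 <- sqrt(var_log) / log(2)
  z <- log2fc / se_log2
  p <- 2 * pnorm(-abs(z))
  p[trt$mean == 0 & ctl$mean == 0] <- 1
  data.frame(
    tss_id = rownames(counts),
    contrast = paste(contrast, collapse = "/"),
    base_mean = base_mean,
    log2fc = log2fc,
    p_value = p,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Call differentially expressed TSSs
#'
#' Benjamini-Hochberg adjustment within each contrast, then the DET rule:
#' `|log2fc| >= lfc_threshold` and `padj <= padj_threshold`.
#'
#' @param results data.frame from [nb_contrast_test] (one or several
#'   contrasts row-bound together).
#' @param lfc_threshold minimal absolute log2 fold change (default 1).
#' @param padj_threshold maximal BH-adjusted p value (default 0.01).
#' @return `results` with `padj` and logical `is_det` columns.
#' @export
call_det <- function(results, lfc_threshold = 1, padj_threshold = 0.01) {
  results$padj <- NA_real_
  for (ct in unique(results$contrast)) {
    idx <- results$contrast == ct
    results$padj[idx] <- p.adjust(results$p_value[idx], method = "BH")
  }
  results$is_det <- abs(results$log2fc) >= lfc_threshold &
    results$padj <= padj_threshold
  results$is_det[is.na(results$is_det)] <- FALSE
  results
}

#' Run the full differential-expression stage
#'
#' Builds the filtered count matrix, normalizes, tests the standard
#' contrasts against control and applies the DET rule.
#'
#' @param master classified master TSS table.
#' @param annotation a [genome_annotation].
#' @param contrasts list of length-2 vectors; default DK/CT, HL/CT, HT/CT.
#' @param min_max_count row filter (see [build_count_matrix]).
#' @param lfc_threshold,padj_threshold DET thresholds.
#' @return list with `counts`, `size_factors` and the combined `results`
#'   data.frame.
#' @export
run_differential_expression <- function(master, annotation,
                                        contrasts = list(c("DK", "CT"),
                                                         c("HL", "CT"),
                                                         c("HT", "CT")),
                                        min_max_count = 300,
                                        lfc_threshold = 1,
                                        padj_threshold = 0.01) {
  counts <- build_count_matrix(master, annotation, min_max_count)
  if (nrow(counts) == 0L) stop("no TSSs pass the count filter")
  sf <- compute_size_factors(counts)
  res <- do.call(rbind, lapply(contrasts, function(ct) {
    nb_contrast_test(counts, sf, ct)
  }))
  res <- call_det(res, lfc_threshold, padj_threshold)
  list(counts = counts, size_factors = sf, results = res)
}
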