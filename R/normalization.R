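# Sample/gene QC filters and the normalization stack: TMM scaling
# factors, logCPM, RPKM, and voom-style precision weights.

#' Filter samples by library size
#'
#' Retains only samples whose total count is strictly greater than
#' `min_total` (default ten million reads, the standard bulk RNA-seq
#' QC cut).
#'
#' @param counts count matrix.
#' @param meta optional metadata, filtered in step with the counts.
#' @param min_total minimum library size (strict `>`).
#' @return List with filtered `counts`, `metadata` (if given) and a
#'   `report` data.frame of per-sample totals and kept flags.
#' @export
filter_library_size <- function(counts, meta = NULL, min_total = 1e7) {
  assert_count_matrix(counts)
  totals <- colSums(counts)
  keep <- totals > min_total
  if (!any(keep)) {
    stopf("all %d samples fall at or below the library-size threshold %g",
          ncol(counts), min_total)
  }
  report <- data.frame(sample_id = colnames(counts), library_size = unname(totals),
                       kept = unname(keep), stringsAsFactors = FALSE)
  out <- list(counts = counts[, keep, drop = FALSE], report = report)
  if (!is.null(meta)) {
    out$metadata <- meta[meta$sample_id %in% colnames(counts)[keep], , drop = FALSE]
    rownames(out$metadata) <- NULL
  }
  out
}

#' Filter genes with low read counts
#'
#' Keeps genes with CPM above the cutoff implied by `min_count` at the
#' median library size in at least as many samples as the smallest
#' group, and with total count at least `min_total_count` — the
#' standard "filterByExpr" rule (implemented via edgeR, with both
#' thresholds configurable).
#'
#' @param counts count matrix.
#' @param group per-sample group labels.
#' @param min_count per-sample count threshold at the median library.
#' @param min_total_count minimum total count across samples.
#' @return List with the filtered `counts` and the logical `kept`
#'   vector (named by gene).
#' @export
filter_low_expression <- function(counts, group, min_count = 10,
                                  min_total_count = 15) {
  assert_count_matrix(counts)
  if (length(group) != ncol(counts)) stopf("group labels must match the samples")
  keep <- edgeR::filterByExpr(counts, group = factor(group),
                              min.count = min_count,
                              min.total.count = min_total_count)
  if (!any(keep)) stopf("no genes pass the low-expression filter")
  names(keep) <- rownames(counts)
  list(counts = counts[keep, , drop = FALSE], kept = keep)
}

#' TMM between-sample normalization factors
#'
#' Trimmed mean of M-values: the reference sample is the one whose
#' upper-quartile CPM is closest to the mean upper-quartile; each
#' sample's factor is the variance-weighted mean of gene-wise
#' log-ratios against the reference after double trimming (by
#' log-ratio and by average expression), and the factors are rescaled
#' to geometric mean one.
#'
#' @param counts count matrix (at least two samples, positive library sums).
#' @param trim_logratio two-sided trim fraction on the log-ratios.
#' @param trim_abs two-sided trim fraction on average log expression.
#' @return Named vector of positive factors with geometric mean 1.
#' @export
tmm_factors <- function(counts, trim_logratio = 0.3, trim_abs = 0.05) {
  assert_count_matrix(counts)
  if (ncol(counts) < 2L) stopf("TMM needs at least two samples")
  if (any(colSums(counts) == 0)) stopf("zero library sum in sample(s): %s",
                                       paste(colnames(counts)[colSums(counts) == 0], collapse = ", "))
  f <- edgeR::calcNormFactors(counts, method = "TMM",
                              logratioTrim = trim_logratio, sumTrim = trim_abs)
  if (any(!is.finite(f)) || any(f <= 0)) {
    stopf("TMM produced non-finite factors; samples may share no expressed genes with the reference")
  }
  setNames(f, colnames(counts))
}

#' log2 counts per million
#'
#' `log2((count + prior) / (effective library + 2 * prior) * 1e6)`,
#' where the effective library is the raw column sum times the TMM
#' factor. With the default prior of 0.5 this matches the logCPM used
#' inside the voom transformation.
#'
#' @param counts count matrix.
#' @param factors per-sample normalization factors (default all 1).
#' @param prior pseudo-count.
#' @return Matrix of logCPM values.
#' @export
logcpm <- function(counts, factors = NULL, prior = 0.5) {
  lib <- colSums(counts) * (factors %||% rep(1, ncol(counts)))
  t(log2(t(counts + prior) / (lib + 2 * prior) * 1e6))
}

#' Reads per kilobase per million mapped reads
#'
#' `count / (gene length in kb * effective library in millions)`;
#' depth- and length-normalized expression used upstream of cell-type
#' enrichment scoring.
#'
#' @param counts count matrix.
#' @param gene_lengths named vector of gene lengths in bases; every
#'   gene in `counts` must be present.
#' @param factors per-sample normalization factors (default all 1).
#' @return Matrix of RPKM values.
#' @export
rpkm <- function(counts, gene_lengths, factors = NULL) {
  missing <- setdiff(rownames(counts), names(gene_lengths))
  if (length(missing)) {
    stopf("missing gene length(s) for: %s", paste(missing, collapse = ", "))
  }
  len_kb <- gene_lengths[rownames(counts)] / 1e3
  lib_m <- colSums(counts) * (factors %||% rep(1, ncol(counts))) / 1e6
  sweep(counts / len_kb, 2, lib_m, "/")
}

#' voom: logCPM with observation-level precision weights
#'
#' Fits a per-gene linear model on logCPM, smooths sqrt(residual SD)
#' against average log2 count with lowess, and converts each
#' observation's predicted standard deviation into an inverse-variance
#' weight (predicted SD to the power -4), enabling normal-theory
#' weighted linear modeling of count data.
#'
#' @param counts count matrix (at least 10 genes, so the
#'   mean-variance trend can be fit).
#' @param factors TMM factors.
#' @param design design matrix (full rank, at least 2 residual df).
#' @param span lowess span for the mean-variance trend.
#' @return A `limma` `EList` with elements `E` (logCPM) and `weights`
#'   (positive precision weights, same shape).
#' @export
voom_weights <- function(counts, factors, design, span = 0.5) {
  assert_count_matrix(counts)
  if (nrow(counts) < 10L) {
    stopf("voom needs at least 10 genes to fit the mean-variance trend (got %d)",
          nrow(counts))
  }
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) stopf("design matrix is not full rank")
  if (ncol(counts) - qrd$rank < 2L) stopf("fewer than 2 residual degrees of freedom")
  v <- limma::voom(counts, design = design,
                   lib.size = colSums(counts) * factors, span = span)
  if (any(!is.finite(v$weights)) || any(v$weights <= 0)) {
    stopf("voom produced non-positive weights")
  }
  v
}
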