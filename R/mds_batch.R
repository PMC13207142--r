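# Batch removal for visualization and classical MDS embedding.

#' Remove the study batch component from a logCPM matrix
#'
#' Fits, per gene, a linear model with the protected covariates
#' (typically the group indicators) plus batch indicators, and
#' subtracts only the fitted batch component, leaving the group
#' structure untouched. Intended for visualization; the differential
#' expression model handles batch by blocking instead. With a single
#' batch the matrix is returned unchanged. The operation is
#' idempotent.
#'
#' @param x logCPM matrix (genes x samples).
#' @param batch per-sample batch (study) labels.
#' @param design protected design matrix (e.g. group indicators);
#'   defaults to an intercept only.
#' @return Corrected matrix, same shape as `x`.
#' @export
remove_batch <- function(x, batch, design = NULL) {
  batch <- droplevels(factor(batch))
  if (length(batch) != ncol(x)) stopf("batch labels must match the samples")
  if (nlevels(batch) < 2L) return(x)
  protect <- design %||% matrix(1, ncol(x), 1)
  B <- stats::model.matrix(~batch)[, -1, drop = FALSE]
  if (qr(cbind(protect, B))$rank < ncol(protect) + ncol(B)) {
    stopf("batch is confounded with the protected design; correction is not identifiable")
  }
  limma::removeBatchEffect(x, batch = batch, design = protect)
}

#' Classical MDS embedding of expression profiles
#'
#' Selects the top `n_top_genes` genes by variance across samples,
#' computes pairwise Euclidean distances, and applies classical
#' scaling (double centering plus eigendecomposition). The first two
#' coordinates are returned with the fraction of variation each
#' explains.
#'
#' @param x (batch-corrected) logCPM matrix, at least 3 samples.
#' @param n_top_genes number of most-variable genes to use; if the
#'   matrix has fewer genes, all are used with a warning.
#' @return Object of class `mds_result`: `coords` (samples x 2),
#'   `explained` (length-2 non-increasing fractions in \[0, 1\]) and
#'   `genes` (the subset used).
#' @export
mds_embed <- function(x, n_top_genes = 500L) {
  if (ncol(x) < 3L) stopf("MDS needs at least 3 samples")
  if (nrow(x) < n_top_genes) {
    warnf("only %d genes available; using all of them", nrow(x))
    n_top_genes <- nrow(x)
  }
  v <- apply(x, 1, stats::var)
  top <- names(sort(v, decreasing = TRUE))[seq_len(n_top_genes)] %||%
    order(v, decreasing = TRUE)[seq_len(n_top_genes)]
  d <- stats::dist(t(x[top, , drop = FALSE]))
  fit <- stats::cmdscale(d, k = 2, eig = TRUE)
  pos <- pmax(fit$eig, 0)
  explained <- if (sum(pos) > 0) pos[1:2] / sum(pos) else c(0, 0)
  coords <- fit$points
  # cmdscale can return fewer columns for degenerate inputs
  if (ncol(coords) < 2L) {
    coords <- cbind(coords, matrix(0, nrow(coords), 2L - ncol(coords)))
  }
  colnames(coords) <- c("dim1", "dim2")
  out <- list(coords = coords, explained = explained, genes = top)
  class(out) <- "mds_result"
  out
}

#' @export
print.mds_result <- function(x, ...) {
  cat(sprintf("classical MDS of %d samples on %d genes; dims explain %.1f%% / %.1f%%\n",
              nrow(x$coords), length(x$genes),
              100 * x$explained[1], 100 * x$explained[2]))
  invisible(x)
}

#' Write MDS coordinates with sample annotations
#'
#' @param mds an [mds_embed()] result.
#' @param meta aligned metadata.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_mds <- function(mds, meta, path) {
  df <- data.frame(sample_id = rownames(mds$coords),
                   dim1 = mds$coords[, 1], dim2 = mds$coords[, 2],
                   stringsAsFactors = FALSE)
  df <- merge(df, meta[, intersect(c("sample_id", "group", "sex", "study"),
                                   colnames(meta))],
              by = "sample_id", sort = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
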