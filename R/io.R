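# Readers and writers for the pipeline's standard artifacts.
#
# TSV dialect: tab-separated, UTF-8, header row, gene ids in the first
# column (featureCounts-style). MatrixMarket counts use a .mtx file
# plus sidecar *_genes.tsv / *_samples.tsv index files.

mtx_sidecars <- function(path) {
  stem <- sub("\\.mtx$", "", path)
  list(genes = paste0(stem, "_genes.tsv"), samples = paste0(stem, "_samples.tsv"))
}

#' Read a gene-by-sample count matrix
#'
#' @param path file path; for `format = "mtx"` the `.mtx` file, with
#'   `*_genes.tsv` and `*_samples.tsv` index files alongside.
#' @param format `"tsv"` or `"mtx"`; guessed from the extension by default.
#' @return Integer matrix with gene rownames and sample colnames.
#' @export
read_counts <- function(path, format = c("auto", "tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path)) "mtx" else "tsv"
  }
  if (!file.exists(path)) stopf("file not found: %s", path)

  if (format == "tsv") {
    nf <- utils::count.fields(path, sep = "\t", quote = "")
    if (length(unique(nf)) > 1L) {
      bad <- which(nf != nf[1])[1]
      stopf("ragged TSV: row %d has %d fields, expected %d", bad, nf[bad], nf[1])
    }
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stopf("count TSV must have a gene-id column plus samples")
    gene_ids <- as.character(df[[1]])
    mat <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(mat)) {
      bad <- which(!vapply(df[-1], is.numeric, logical(1)))[1] + 1L
      stopf("non-numeric entries in column '%s'", colnames(df)[bad])
    }
    nonint <- which(mat != round(mat), arr.ind = TRUE)
    if (nrow(nonint) > 0L) {
      stopf("non-integer count for gene '%s', sample '%s'",
            gene_ids[nonint[1, 1]], colnames(mat)[nonint[1, 2]])
    }
    rownames(mat) <- gene_ids
  } else {
    side <- mtx_sidecars(path)
    if (!file.exists(side$genes) || !file.exists(side$samples)) {
      stopf("missing MTX index files %s / %s", side$genes, side$samples)
    }
    m <- read_matrix_market(path)
    rownames(m) <- readLines(side$genes)
    colnames(m) <- readLines(side$samples)
    mat <- m
  }
  storage.mode(mat) <- "integer"
  assert_count_matrix(mat)
  mat
}

# Minimal MatrixMarket coordinate reader (integer/real general). Kept
# dependency-free so MTX round trips do not require the Matrix package.
read_matrix_market <- function(path) {
  lines <- readLines(path)
  header <- lines[1]
  if (!grepl("^%%MatrixMarket\\s+matrix\\s+coordinate", header)) {
    stopf("not a MatrixMarket coordinate file: %s", path)
  }
  body <- lines[!startsWith(lines, "%")]
  dims <- scan(text = body[1], quiet = TRUE)
  m <- matrix(0, nrow = dims[1], ncol = dims[2])
  if (dims[3] > 0) {
    trip <- matrix(scan(text = body[-1], quiet = TRUE), ncol = 3, byrow = TRUE)
    m[cbind(trip[, 1], trip[, 2])] <- trip[, 3]
  }
  m
}

#' Write a count matrix
#'
#' `write_counts` and [read_counts()] are exact inverses for valid
#' integer matrices, in both formats.
#'
#' @param counts integer matrix with dimnames.
#' @param path output path (`.mtx` for MatrixMarket).
#' @param format `"tsv"` or `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  assert_count_matrix(counts)
  if (format == "tsv") {
    df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    side <- mtx_sidecars(path)
    nz <- which(counts != 0, arr.ind = TRUE)
    nz <- nz[order(nz[, 2], nz[, 1]), , drop = FALSE]
    con <- file(path, "w")
    writeLines("%%MatrixMarket matrix coordinate integer general", con)
    writeLines(sprintf("%d %d %d", nrow(counts), ncol(counts), nrow(nz)), con)
    if (nrow(nz) > 0) {
      writeLines(sprintf("%d %d %d", nz[, 1], nz[, 2], counts[nz]), con)
    }
    close(con)
    writeLines(rownames(counts), side$genes)
    writeLines(colnames(counts), side$samples)
  }
  invisible(path)
}

#' Read / write per-sample metadata
#'
#' Metadata is a TSV with columns `sample_id`, `study`, `condition`
#' (`PS`/`Control`) and `sex` (`male`/`female`/`unknown`; unknown sex
#' is always encoded explicitly, never as an empty cell). The derived
#' `group` column (e.g. `PS_male`) is defined only where sex is known.
#'
#' @param path file path.
#' @return `read_metadata`: data.frame with a `group` column added.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_metadata(df)
}

#' @rdname read_metadata
#' @param meta metadata data.frame.
#' @export
write_metadata <- function(meta, path) {
  meta <- validate_metadata(meta)
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_metadata <- function(meta) {
  need <- c("sample_id", "study", "condition", "sex")
  miss <- setdiff(need, colnames(meta))
  if (length(miss)) stopf("metadata missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(meta$sample_id)) {
    stopf("duplicate sample ids in metadata: %s",
          paste(unique(meta$sample_id[duplicated(meta$sample_id)]), collapse = ", "))
  }
  bad <- setdiff(unique(meta$condition), c("PS", "Control"))
  if (length(bad)) stopf("condition must be PS or Control, found: %s", paste(bad, collapse = ", "))
  bad <- setdiff(unique(meta$sex), c("male", "female", "unknown"))
  if (length(bad)) stopf("sex must be male, female or unknown, found: %s", paste(bad, collapse = ", "))
  meta$group <- derive_group(meta$condition, meta$sex)
  meta
}

#' Derive the four-group label from condition and sex
#'
#' @param condition `PS`/`Control` vector.
#' @param sex `male`/`female`/`unknown` vector.
#' @return Character vector of `PS_male`-style labels, `NA` where sex
#'   is unknown.
#' @export
derive_group <- function(condition, sex) {
  ifelse(sex == "unknown", NA_character_, paste(condition, sex, sep = "_"))
}

#' Check and align a count matrix with its metadata
#'
#' Verifies that the sample sets are identical, reorders the metadata
#' rows to the column order of the counts and returns the aligned pair.
#' Missing or extra samples are reported by id.
#'
#' @param counts count matrix.
#' @param meta metadata data.frame.
#' @return List with aligned `counts` and `metadata`.
#' @export
validate_pairing <- function(counts, meta) {
  assert_count_matrix(counts)
  meta <- validate_metadata(meta)
  missing <- setdiff(colnames(counts), meta$sample_id)
  extra <- setdiff(meta$sample_id, colnames(counts))
  if (length(missing)) {
    stopf("metadata is missing sample(s): %s", paste(missing, collapse = ", "))
  }
  if (length(extra)) {
    stopf("metadata has sample(s) absent from counts: %s", paste(extra, collapse = ", "))
  }
  meta <- meta[match(colnames(counts), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  list(counts = counts, metadata = meta)
}

#' Read / write gene annotation (gene lengths)
#'
#' TSV with columns `gene_id` and `gene_length` (bases, positive).
#'
#' @param path file path.
#' @return Named numeric vector of gene lengths.
#' @export
read_gene_lengths <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "gene_length") %in% colnames(df))) {
    stopf("gene annotation must have columns gene_id and gene_length")
  }
  if (any(df$gene_length <= 0)) stopf("gene lengths must be positive")
  setNames(df$gene_length, df$gene_id)
}

#' Read a pipeline configuration from YAML
#'
#' The YAML sections mirror the pipeline stages (`sim`, `filters`,
#' `sex_inference`, `de`, `mds`, `composition`); missing keys fall back
#' to [default_config()] values, which carry the standard analysis
#' thresholds (10-million library filter, |log2FC| > 1, adjusted
#' p < 0.05, probability threshold 0.5).
#'
#' @param path YAML file path.
#' @return Configuration list as used by [run_pipeline()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  user <- yaml::read_yaml(path)
  modifyList(default_config(), user)
}
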