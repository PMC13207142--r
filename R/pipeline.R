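# End-to-end orchestration: simulate/load -> QC -> sex inference ->
# normalization -> DE with interaction -> MDS -> cell composition.

#' Default pipeline configuration
#'
#' Every standard analysis threshold is surfaced here with its
#' conventional value as default: the 10-million library filter, the
#' |log2FC| > 1 and adjusted p < 0.05 DEG rule, and the 0.5
#' probability threshold for calling female.
#'
#' @return Nested configuration list with sections `sim`, `filters`,
#'   `sex_inference`, `de`, `mds` and `composition`.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    simulate = TRUE,
    sim = simulation_config(),
    filters = list(min_library = 1e7, min_count = 10, min_total_count = 15),
    sex_inference = list(enabled = TRUE, n_folds = 10L, threshold = 0.5),
    de = list(lfc_threshold = 1, alpha = 0.05),
    mds = list(n_top_genes = 500L),
    composition = list(enabled = TRUE, n_cell_types = 64L, score_sd = 0.05)
  )
}

pipeline_stage <- function(name, expr, verbose = FALSE) {
  if (verbose) message(sprintf("[sexstrat] stage: %s", name))
  tryCatch(expr, error = function(e) {
    stopf("stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run the full sex-stratified analysis pipeline
#'
#' Stages, in order: data simulation (or user-supplied counts and
#' metadata), library-size QC, expression-based inference of any
#' unknown sex labels (a classifier trained on the reported-sex
#' samples), low-expression gene filtering, TMM + voom, study-blocked
#' weighted linear modeling with the female/male/interaction
#' contrasts, DEG calling and Venn partitioning, batch-corrected MDS,
#' and cell-type composition statistics. All randomness is controlled
#' by the config seeds, so re-running with the same config and inputs
#' reproduces the outputs exactly.
#'
#' @param config configuration list as from [default_config()] or
#'   [read_config()].
#' @param counts,meta optional user data (used when
#'   `config$simulate` is `FALSE`).
#' @param scores optional cell-type score matrix whose columns are
#'   samples in `meta`; when simulating, scores are generated.
#' @param out_dir optional directory; when given, stage outputs are
#'   written as TSV/JSON files.
#' @param verbose log stage progression to stderr.
#' @return Object of class `run_report`: per-stage dimensions,
#'   thresholds used, classifier metrics, per-contrast DEG counts and
#'   partition, significant cell types, seeds and package version,
#'   plus the stage outputs themselves.
#' @export
run_pipeline <- function(config = default_config(), counts = NULL, meta = NULL,
                         scores = NULL, out_dir = NULL, verbose = FALSE) {
  cfg <- modifyList(default_config(), config)
  report <- list(seeds = list(pipeline = cfg$seed,
                              sim = if (isTRUE(cfg$simulate)) cfg$sim$seed else NA),
                 thresholds = cfg$filters,
                 de_thresholds = cfg$de,
                 version = as.character(utils::packageVersion("sexstrat")))

  sim <- NULL
  if (isTRUE(cfg$simulate)) {
    sim <- pipeline_stage("simulate", generate_counts(cfg$sim), verbose)
    counts <- sim$counts
    meta <- sim$metadata
  } else if (is.null(counts) || is.null(meta)) {
    stopf("config$simulate is FALSE but no counts/metadata were supplied")
  }
  pair <- pipeline_stage("validate", validate_pairing(counts, meta), verbose)
  report$input_dim <- dim(pair$counts)

  qc <- pipeline_stage("library_filter",
                       filter_library_size(pair$counts, pair$metadata,
                                           min_total = cfg$filters$min_library),
                       verbose)
  report$samples_removed_library <- sum(!qc$report$kept)
  counts <- qc$counts
  meta <- qc$metadata

  if (isTRUE(cfg$sex_inference$enabled) && any(meta$sex == "unknown")) {
    meta <- pipeline_stage("sex_inference", {
      known <- meta$sex != "unknown"
      if (sum(known) < 4L || length(unique(meta$sex[known])) < 2L) {
        stopf("not enough reported-sex samples to train the classifier")
      }
      X <- extract_sex_features(counts[, meta$sample_id[known], drop = FALSE])
      n_min <- min(table(meta$sex[known]))
      model <- fit_lasso_logistic(X, meta$sex[known],
                                  n_folds = min(cfg$sex_inference$n_folds, n_min),
                                  seed = cfg$seed,
                                  threshold = cfg$sex_inference$threshold)
      report$classifier <- evaluate_classifier(
        predict_sex(model, X), meta$sex[known])
      report$sex_model <- model
      infer_missing_sex(counts, meta, model)
    }, verbose)
  } else {
    meta$sex_source <- "reported"
  }
  report$group_counts <- table(factor(meta$group, levels = group_levels()))

  de <- pipeline_stage("differential_expression",
                       run_de(counts, meta,
                              lfc_threshold = cfg$de$lfc_threshold,
                              alpha = cfg$de$alpha,
                              min_count = cfg$filters$min_count,
                              min_total_count = cfg$filters$min_total_count),
                       verbose)
  report$genes_tested <- nrow(de$tables$female)
  report$deg_counts <- vapply(de$degs, length, integer(1))
  report$partition_counts <- de$partition$counts

  mds <- pipeline_stage("mds", {
    lc <- de$voom$E
    corrected <- remove_batch(lc, meta$study, design = de$design[, group_levels(), drop = FALSE])
    mds_embed(corrected, n_top_genes = min(cfg$mds$n_top_genes, nrow(corrected)))
  }, verbose)
  report$mds_explained <- mds$explained

  comp <- NULL
  if (isTRUE(cfg$composition$enabled)) {
    comp <- pipeline_stage("composition", {
      if (is.null(scores)) {
        if (is.null(sim)) {
          NULL  # nothing to analyze
        } else {
          grp_sizes <- table(factor(meta$group, levels = group_levels()))
          es <- generate_enrichment_scores(
            n_cell_types = cfg$composition$n_cell_types,
            group_sizes = setNames(as.integer(grp_sizes), names(grp_sizes)),
            score_sd = cfg$composition$score_sd,
            seed = cfg$seed)
          composition_stats(es$scores, es$metadata)
        }
      } else {
        composition_stats(scores, meta)
      }
    }, verbose)
    if (!is.null(comp)) {
      report$composition_significant <- comp$effects$cell_type[comp$effects$significant]
    }
  }

  report$outputs <- list(metadata = meta, de = de, mds = mds, composition = comp,
                         library_report = qc$report)
  class(report) <- "run_report"

  if (!is.null(out_dir)) write_run_outputs(report, out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("sexstrat run report\n")
  cat(sprintf("  input: %d genes x %d samples; %d sample(s) removed by the library filter\n",
              x$input_dim[1], x$input_dim[2], x$samples_removed_library))
  cat("  group sizes:", paste(sprintf("%s=%d", names(x$group_counts), x$group_counts),
                              collapse = ", "), "\n")
  cat(sprintf("  genes tested: %d\n", x$genes_tested))
  cat("  DEGs:", paste(sprintf("%s=%d", names(x$deg_counts), x$deg_counts),
                       collapse = ", "), "\n")
  cat("  partition:", paste(sprintf("%s=%d", names(x$partition_counts), x$partition_counts),
                            collapse = ", "), "\n")
  if (!is.null(x$composition_significant)) {
    cat(sprintf("  composition: %d cell type(s) with FDR < 0.05\n",
                length(x$composition_significant)))
  }
  invisible(x)
}

write_run_outputs <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  o <- report$outputs
  write_metadata(o$metadata[, c("sample_id", "study", "condition", "sex")],
                 file.path(out_dir, "metadata.tsv"))
  utils::write.table(o$library_report, file.path(out_dir, "library_filter.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (cn in names(o$de$tables)) {
    utils::write.table(o$de$tables[[cn]],
                       file.path(out_dir, sprintf("de_%s.tsv", cn)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(o$de$partition$partition,
                     file.path(out_dir, "deg_partition.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(deg_counts = as.list(report$deg_counts),
         partition_counts = as.list(report$partition_counts),
         group_counts = as.list(setNames(as.integer(report$group_counts),
                                         names(report$group_counts))),
         seeds = report$seeds, version = report$version),
    file.path(out_dir, "run_report.json"), auto_unbox = TRUE, digits = NA)
  write_mds(o$mds, o$metadata, file.path(out_dir, "mds.tsv"))
  if (!is.null(o$composition)) {
    utils::write.table(o$composition$effects,
                       file.path(out_dir, "composition_effects.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(out_dir)
}
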