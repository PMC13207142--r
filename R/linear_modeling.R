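# Study-blocked weighted linear modeling, empirical-Bayes moderation,
# the sex-specific and interaction contrasts, DEG calling and the
# Venn/direction partition.

#' Build the group-means design with study blocking
#'
#' One indicator per design group (group-means, no intercept) so the
#' contrasts can be written exactly as group differences, plus
#' `n_studies - 1` study indicators modeling inter-study variation as
#' a nuisance (blocking) term. Rank is checked and collinear columns
#' are named in the error.
#'
#' @param meta metadata with known sex for every sample.
#' @return Design matrix with a `"study_cols"` attribute marking the
#'   blocking columns.
#' @export
build_design <- function(meta) {
  if (any(meta$sex == "unknown") || any(is.na(meta$group))) {
    stopf("all samples need a known sex before the design can be built")
  }
  grp <- factor(meta$group, levels = intersect(group_levels(), unique(meta$group)))
  X <- stats::model.matrix(~ 0 + grp)
  colnames(X) <- levels(grp)
  study_cols <- character(0)
  studies <- unique(meta$study)
  if (length(studies) > 1L) {
    st <- factor(meta$study, levels = studies)
    S <- stats::model.matrix(~st)[, -1, drop = FALSE]
    colnames(S) <- paste0("study_", levels(st)[-1])
    study_cols <- colnames(S)
    X <- cbind(X, S)
  }
  rownames(X) <- meta$sample_id
  qrd <- qr(X)
  if (qrd$rank < ncol(X)) {
    bad <- colnames(X)[qrd$pivot[(qrd$rank + 1):ncol(X)]]
    stopf("design matrix is rank deficient; collinear column(s): %s",
          paste(bad, collapse = ", "))
  }
  attr(X, "study_cols") <- study_cols
  X
}

#' The three standard contrasts (female, male, interaction)
#'
#' `female = PS_female - Control_female`, `male = PS_male -
#' Control_male`, and `interaction = male - female`, i.e.
#' `(PS_male - Control_male) - (PS_female - Control_female)`; study
#' blocking columns never enter a contrast.
#'
#' @param design design matrix from [build_design()].
#' @return Contrast matrix (design columns x 3).
#' @export
make_group_contrasts <- function(design) {
  cn <- colnames(design)
  need <- group_levels()
  miss <- setdiff(need, cn)
  if (length(miss)) stopf("design lacks group column(s): %s", paste(miss, collapse = ", "))
  contr <- matrix(0, nrow = length(cn), ncol = 3,
                  dimnames = list(cn, c("female", "male", "interaction")))
  contr["PS_female", "female"] <- 1
  contr["Control_female", "female"] <- -1
  contr["PS_male", "male"] <- 1
  contr["Control_male", "male"] <- -1
  contr[, "interaction"] <- contr[, "male"] - contr[, "female"]
  contr
}

#' Per-gene weighted least squares
#'
#' Fits every gene by weighted least squares against the design,
#' honoring the observation weights carried by a voom `EList`.
#' Residual degrees of freedom are `n - rank(design)`.
#'
#' @param y voom `EList` (or a plain matrix for unit weights).
#' @param design full-rank design matrix.
#' @return A `limma` `MArrayLM` fit: coefficients, residual SDs
#'   (`sigma`), residual df and unscaled coefficient standard errors.
#' @export
fit_weighted_lm <- function(y, design) {
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) stopf("design matrix is not full rank")
  n <- if (is.matrix(y)) ncol(y) else ncol(y$E)
  if (n - qrd$rank <= 0L) stopf("no residual degrees of freedom (n = %d, rank = %d)",
                                n, qrd$rank)
  limma::lmFit(y, design)
}

#' Empirical-Bayes variance moderation
#'
#' Shrinks per-gene residual variances toward a prior estimated by
#' moment matching on the log variances (digamma/trigamma inversion),
#' giving moderated t-statistics with `d0 + d_g` degrees of freedom.
#' When all variances are identical the prior df is infinite and every
#' posterior variance equals the prior variance.
#'
#' @param fit an [fit_weighted_lm()] (or contrast) fit with at least
#'   10 genes.
#' @return The fit augmented with `df.prior`, `s2.prior`, `s2.post`,
#'   moderated `t` and `p.value`.
#' @export
ebayes_moderate <- function(fit) {
  if (nrow(fit$coefficients) < 10L) {
    stopf("empirical-Bayes moderation needs at least 10 genes (got %d)",
          nrow(fit$coefficients))
  }
  limma::eBayes(fit)
}

#' Estimate contrasts and return per-contrast moderated tables
#'
#' Rotates the fitted coefficients onto the requested contrasts
#' (log-fold-changes are linear in the coefficients, variances come
#' from the contrast quadratic form), applies empirical-Bayes
#' moderation, and tabulates logFC, moderated t, raw and BH-adjusted p
#' per contrast. Contrasts that touch study blocking columns are
#' rejected.
#'
#' @param fit an unmoderated [fit_weighted_lm()] fit.
#' @param contrasts contrast matrix with rownames matching the design
#'   columns (see [make_group_contrasts()]).
#' @return Named list of per-contrast data.frames
#'   (`gene`, `logFC`, `t`, `p`, `adj_p`).
#' @export
apply_contrasts <- function(fit, contrasts) {
  contrasts <- as.matrix(contrasts)
  design_cols <- colnames(fit$coefficients)
  if (!identical(rownames(contrasts), design_cols)) {
    stopf("contrast rows must match the design columns")
  }
  study_cols <- attr(fit$design, "study_cols") %||%
    grep("^study_", design_cols, value = TRUE)
  if (length(study_cols) && any(contrasts[study_cols, , drop = FALSE] != 0)) {
    stopf("contrasts must not involve study blocking columns")
  }
  cf <- limma::contrasts.fit(fit, contrasts)
  eb <- ebayes_moderate(cf)
  out <- lapply(colnames(contrasts), function(cn) {
    p <- eb$p.value[, cn]
    data.frame(gene = rownames(eb$coefficients),
               logFC = eb$coefficients[, cn],
               t = eb$t[, cn],
               p = p,
               adj_p = bh_adjust(p),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  names(out) <- colnames(contrasts)
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement; order
#' preserving, adjusted values never below the raw values.
#'
#' @param p vector of p-values in \[0, 1\].
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stopf("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Call differentially expressed genes
#'
#' A gene is a DEG iff `|log2FC| > lfc_threshold` AND adjusted
#' p `< alpha`, both inequalities strict. Direction is `Up`/`Down` by
#' the sign of the log fold change, `n.s.` otherwise.
#'
#' @param table per-contrast table from [apply_contrasts()].
#' @param lfc_threshold log2 fold-change threshold (strict `>`).
#' @param alpha adjusted-p threshold (strict `<`).
#' @return The table with `deg` (logical) and `direction` columns added.
#' @export
call_degs <- function(table, lfc_threshold = 1, alpha = 0.05) {
  table$deg <- abs(table$logFC) > lfc_threshold & table$adj_p < alpha
  table$direction <- ifelse(!table$deg, "n.s.",
                            ifelse(table$logFC > 0, "Up", "Down"))
  table
}

#' Partition DEGs between the two sex-specific comparisons
#'
#' Three-way Venn partition (female-only, male-only, overlap) with
#' per-sex direction labels in the `"Up (M) Down (F)"` style and a
#' directional-consistency flag for overlap genes. Consistency is
#' reported, not filtered on.
#'
#' @param female_table,male_table [call_degs()]-annotated tables for
#'   the female and male contrasts.
#' @return List with `partition` (per-gene membership, directions,
#'   label, consistency) and `counts` (`female_only`, `male_only`,
#'   `overlap`).
#' @export
partition_degs <- function(female_table, male_table) {
  f_deg <- female_table$gene[female_table$deg]
  m_deg <- male_table$gene[male_table$deg]
  genes <- union(f_deg, m_deg)
  membership <- ifelse(genes %in% f_deg & genes %in% m_deg, "overlap",
                       ifelse(genes %in% f_deg, "female-only", "male-only"))
  dir_f <- female_table$direction[match(genes, female_table$gene)]
  dir_m <- male_table$direction[match(genes, male_table$gene)]

  label <- character(length(genes))
  for (i in seq_along(genes)) {
    label[i] <- switch(membership[i],
      "female-only" = sprintf("%s (F)", dir_f[i]),
      "male-only" = sprintf("%s (M)", dir_m[i]),
      "overlap" = if (dir_f[i] == dir_m[i]) sprintf("%s (M, F)", dir_m[i])
                  else sprintf("%s (M) %s (F)", dir_m[i], dir_f[i])
    )
  }
  consistent <- ifelse(membership == "overlap", dir_f == dir_m, NA)

  partition <- data.frame(gene = genes, membership = membership,
                          direction_female = dir_f, direction_male = dir_m,
                          label = label, consistent = consistent,
                          stringsAsFactors = FALSE)
  counts <- c(female_only = sum(membership == "female-only"),
              male_only = sum(membership == "male-only"),
              overlap = sum(membership == "overlap"))
  list(partition = partition, counts = counts)
}

#' Full differential-expression run on a filtered dataset
#'
#' Convenience wrapper chaining the low-expression filter, TMM, voom
#' with the study-blocked group-means design, weighted least squares,
#' the three contrasts, and DEG calling.
#'
#' @param counts count matrix (library-size filtered).
#' @param meta aligned metadata with known sex.
#' @param lfc_threshold,alpha DEG thresholds (see [call_degs()]).
#' @param min_count,min_total_count gene-filter thresholds.
#' @return List with `tables` (per-contrast DEG-annotated tables),
#'   `degs` (per-contrast DEG id sets), `partition`, `design`,
#'   `factors` and the voom `EList`.
#' @export
run_de <- function(counts, meta, lfc_threshold = 1, alpha = 0.05,
                   min_count = 10, min_total_count = 15) {
  pair <- validate_pairing(counts, meta)
  flt <- filter_low_expression(pair$counts, pair$metadata$group,
                               min_count = min_count,
                               min_total_count = min_total_count)
  factors <- tmm_factors(flt$counts)
  design <- build_design(pair$metadata)
  v <- voom_weights(flt$counts, factors, design)
  fit <- fit_weighted_lm(v, design)
  fit$design <- design
  tables <- apply_contrasts(fit, make_group_contrasts(design))
  tables <- lapply(tables, call_degs, lfc_threshold = lfc_threshold, alpha = alpha)
  degs <- lapply(tables, function(tb) tb$gene[tb$deg])
  list(tables = tables, degs = degs,
       partition = partition_degs(tables$female, tables$male),
       design = design, factors = factors, voom = v)
}

jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(1)
  length(intersect(a, b)) / u
}

#' Balanced-dataset sensitivity analysis
#'
#' Subsamples without replacement to equal male/female numbers within
#' each condition (drawing evenly across studies where possible),
#' re-runs the full differential-expression pipeline on the balanced
#' subset, and reports the Jaccard overlap of the DEG sets with the
#' full-data run. An already balanced dataset is returned intact, so
#' results are identical to the full run.
#'
#' @param counts count matrix.
#' @param meta aligned metadata with known sex.
#' @param seed integer seed for the subsample.
#' @param ... passed to [run_de()].
#' @return List with the balanced run (`balanced`), the full run
#'   (`full`), per-contrast `jaccard`, and the ids kept.
#' @export
balanced_sensitivity <- function(counts, meta, seed = 1L, ...) {
  pair <- validate_pairing(counts, meta)
  meta <- pair$metadata
  keep <- with_seed(seed, {
    kept <- character(0)
    for (cond in unique(meta$condition)) {
      sub <- meta[meta$condition == cond, , drop = FALSE]
      n_m <- sum(sub$sex == "male")
      n_f <- sum(sub$sex == "female")
      if (n_m == 0L || n_f == 0L) {
        stopf("condition %s has a single sex; balancing is impossible", cond)
      }
      n_target <- min(n_m, n_f)
      for (sx in c("male", "female")) {
        ids <- sub$sample_id[sub$sex == sx]
        if (length(ids) > n_target) {
          # draw evenly across studies where possible
          by_study <- split(ids, sub$study[sub$sex == sx])
          picked <- character(0)
          quota <- n_target
          for (st in names(by_study)) {
            share <- min(length(by_study[[st]]),
                         ceiling(quota * length(by_study[[st]]) / length(ids)))
            picked <- c(picked, sample(by_study[[st]],
                                       min(share, length(by_study[[st]]))))
          }
          picked <- unique(picked)
          if (length(picked) > n_target) picked <- sample(picked, n_target)
          if (length(picked) < n_target) {
            picked <- c(picked, sample(setdiff(ids, picked), n_target - length(picked)))
          }
          ids <- picked
        }
        kept <- c(kept, ids)
      }
    }
    kept
  })
  keep <- colnames(counts)[colnames(counts) %in% keep]  # preserve column order
  full <- run_de(pair$counts, meta, ...)
  bal_meta <- meta[match(keep, meta$sample_id), , drop = FALSE]
  balanced <- run_de(pair$counts[, keep, drop = FALSE], bal_meta, ...)
  jac <- vapply(names(full$degs), function(cn) {
    jaccard(full$degs[[cn]], balanced$degs[[cn]])
  }, numeric(1))
  list(balanced = balanced, full = full, jaccard = jac, kept_samples = keep)
}
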