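#' The six sex-chromosome marker genes
#'
#' XIST is expressed essentially only in female samples (it drives
#' X-chromosome inactivation); the five Y-linked genes EIF1AY, KDM5D,
#' UTY, DDX3Y and RPS4Y1 are expressed essentially only in males.
#' Their logCPM values are the feature set for expression-based sex
#' calling, and the simulator plants exactly this structure.
#'
#' @return Named character vector mapping gene symbol to the sex in
#'   which the gene is expressed, XIST first.
#' @export
#' @examples
#' sex_marker_genes()
sex_marker_genes <- function() {
  c(XIST = "female", EIF1AY = "male", KDM5D = "male",
    UTY = "male", DDX3Y = "male", RPS4Y1 = "male")
}

#' Simulation configuration for the multi-study count generator
#'
#' Defines the statistical structure the downstream analysis assumes:
#' several studies with multiplicative (log-additive) batch effects,
#' four groups (psoriasis/control crossed with male/female), planted
#' shared, female-only and male-only disease DEGs, planted
#' sex-by-disease interaction genes, and the six sex-exclusive marker
#' genes.
#'
#' @param n_studies number of studies (batches).
#' @param samples_per_group_per_study either a named vector over the
#'   four groups (`PS_male`, `PS_female`, `Control_male`,
#'   `Control_female`) used for every study, or an `n_studies` x 4
#'   matrix (columns named by group) for uneven designs.
#' @param n_genes total number of genes, including the six markers.
#' @param n_shared_degs,n_female_unique_degs,n_male_unique_degs numbers
#'   of planted disease DEGs shared by both sexes / specific to each sex.
#' @param n_interaction_genes number of genes whose disease response
#'   differs between the sexes.
#' @param deg_log2fc magnitude of the planted disease log2 fold changes.
#' @param interaction_log2fc difference between the male and female
#'   disease log2FC at planted interaction genes.
#' @param batch_sd standard deviation of the per-study, per-gene
#'   log2-scale offsets (0 disables batch effects).
#' @param dispersion negative-binomial dispersion phi (variance
#'   mu + phi * mu^2); a single common value across genes.
#' @param lib_size_range range of library sizes; sizes are drawn
#'   log-uniformly so the 10-million-read library filter can be
#'   exercised by setting the lower end below 1e7.
#' @param marker_logcpm_high target logCPM of a sex marker in the sex
#'   that expresses it.
#' @param marker_noise_floor expected CPM of a sex marker in the
#'   opposite sex (0 means fully silent; values at or below 0.1 keep
#'   the realized off-sex logCPM at or below roughly 0.1).
#' @param seed integer RNG seed; identical seed and config give
#'   byte-identical output.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(n_studies = 3L,
                              samples_per_group_per_study = c(
                                PS_male = 8L, PS_female = 8L,
                                Control_male = 8L, Control_female = 8L),
                              n_genes = 2000L,
                              n_shared_degs = 100L,
                              n_female_unique_degs = 30L,
                              n_male_unique_degs = 30L,
                              n_interaction_genes = 10L,
                              deg_log2fc = 2,
                              interaction_log2fc = 2,
                              batch_sd = 0.5,
                              dispersion = 0.1,
                              lib_size_range = c(8e6, 3e7),
                              marker_logcpm_high = 8,
                              marker_noise_floor = 0.1,
                              seed = 1L) {
  cfg <- list(
    n_studies = as.integer(n_studies),
    samples_per_group_per_study = samples_per_group_per_study,
    n_genes = as.integer(n_genes),
    n_shared_degs = as.integer(n_shared_degs),
    n_female_unique_degs = as.integer(n_female_unique_degs),
    n_male_unique_degs = as.integer(n_male_unique_degs),
    n_interaction_genes = as.integer(n_interaction_genes),
    deg_log2fc = deg_log2fc,
    interaction_log2fc = interaction_log2fc,
    batch_sd = batch_sd,
    dispersion = dispersion,
    lib_size_range = lib_size_range,
    marker_logcpm_high = marker_logcpm_high,
    marker_noise_floor = marker_noise_floor,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  grp <- group_levels()
  sz <- cfg$samples_per_group_per_study
  if (is.matrix(sz)) {
    if (nrow(sz) != cfg$n_studies || !all(grp %in% colnames(sz))) {
      stopf("samples_per_group_per_study matrix must have n_studies rows and columns %s",
            paste(grp, collapse = ", "))
    }
    sz <- sz[, grp, drop = FALSE]
  } else {
    if (!all(grp %in% names(sz))) {
      stopf("samples_per_group_per_study must name the four groups %s",
            paste(grp, collapse = ", "))
    }
    sz <- matrix(rep(as.numeric(sz[grp]), each = cfg$n_studies),
                 nrow = cfg$n_studies, dimnames = list(NULL, grp))
  }
  if (any(sz < 0) || any(sz != round(sz))) {
    stopf("group sizes must be non-negative integers")
  }
  if (cfg$n_studies < 1L) stopf("n_studies must be positive")
  if (cfg$dispersion <= 0) stopf("dispersion must be > 0, got %g", cfg$dispersion)
  n_planted <- cfg$n_shared_degs + cfg$n_female_unique_degs +
    cfg$n_male_unique_degs + cfg$n_interaction_genes
  if (cfg$n_genes < n_planted + length(sex_marker_genes())) {
    stopf(paste0("n_genes (%d) is smaller than the %d planted genes plus the ",
                 "%d sex markers"),
          cfg$n_genes, n_planted, length(sex_marker_genes()))
  }
  if (cfg$batch_sd < 0) stopf("batch_sd must be >= 0")
  if (cfg$marker_noise_floor < 0) stopf("marker_noise_floor must be >= 0")
  if (length(cfg$lib_size_range) != 2L || any(cfg$lib_size_range <= 0) ||
      cfg$lib_size_range[1] > cfg$lib_size_range[2]) {
    stopf("lib_size_range must be an increasing pair of positive numbers")
  }
  invisible(cfg)
}

# Expand the per-study group sizes into a study x group integer matrix.
sim_group_matrix <- function(cfg) {
  grp <- group_levels()
  sz <- cfg$samples_per_group_per_study
  if (is.matrix(sz)) {
    out <- sz[, grp, drop = FALSE]
  } else {
    out <- matrix(rep(as.integer(sz[grp]), each = cfg$n_studies),
                  nrow = cfg$n_studies, dimnames = list(NULL, grp))
  }
  storage.mode(out) <- "integer"
  out
}

#' Generate a synthetic multi-study count dataset with known truth
#'
#' Counts are drawn from a negative-binomial model: per-gene baseline
#' abundance (on the CPM scale) times a per-study, per-gene batch
#' multiplier `2^N(0, batch_sd)`, times the planted group-effect
#' multiplier, scaled to a log-uniform library size. The XIST analog
#' is high only in females and the five Y-gene analogs high only in
#' males, with opposite-sex expression at `marker_noise_floor` CPM.
#' Planted interaction genes have disease log2FCs that differ between
#' the sexes by `interaction_log2fc`.
#'
#' @param config a [simulation_config()].
#' @return A list with elements `counts` (gene x sample integer
#'   matrix), `metadata` (data.frame with `sample_id`, `study`,
#'   `condition`, `sex`, `group`) and `truth` (planted marker genes,
#'   DEG sets with directions, per-sex interaction log2FCs, per-sample
#'   true sex, per-study batch offsets, library sizes and baseline CPM).
#' @export
#' @examples
#' sim <- generate_counts(simulation_config(n_studies = 1,
#'   samples_per_group_per_study = c(PS_male = 3, PS_female = 3,
#'     Control_male = 3, Control_female = 3),
#'   n_genes = 300, n_shared_degs = 10, n_female_unique_degs = 5,
#'   n_male_unique_degs = 5, n_interaction_genes = 2, seed = 7))
#' dim(sim$counts)
generate_counts <- function(config) {
  validate_sim_config(config)
  with_seed(config$seed, generate_counts_impl(config))
}

generate_counts_impl <- function(cfg) {
  markers <- sex_marker_genes()
  n_mark <- length(markers)
  grp <- group_levels()
  sizes <- sim_group_matrix(cfg)
  studies <- sprintf("study%02d", seq_len(cfg$n_studies))

  gene_ids <- c(names(markers),
                sprintf("GENE%05d", seq_len(cfg$n_genes - n_mark)))

  # sample sheet ------------------------------------------------------------
  meta <- do.call(rbind, lapply(seq_len(cfg$n_studies), function(s) {
    do.call(rbind, lapply(grp, function(g) {
      n <- sizes[s, g]
      if (n == 0L) return(NULL)
      data.frame(study = studies[s], group = g, stringsAsFactors = FALSE)[rep(1, n), ]
    }))
  }))
  rownames(meta) <- NULL
  meta$condition <- ifelse(startsWith(meta$group, "PS"), "PS", "Control")
  meta$sex <- ifelse(endsWith(meta$group, "female"), "female", "male")
  meta$sample_id <- sprintf("S%03d_%s", seq_len(nrow(meta)), meta$group)
  meta <- meta[, c("sample_id", "study", "condition", "sex", "group")]
  n_samples <- nrow(meta)
  if (n_samples == 0L) stopf("configuration yields zero samples")

  # planted gene sets (disjoint, never touching the markers) ----------------
  pool <- gene_ids[-seq_len(n_mark)]
  n_planted <- cfg$n_shared_degs + cfg$n_female_unique_degs +
    cfg$n_male_unique_degs + cfg$n_interaction_genes
  planted <- if (n_planted > 0L) sample(pool, n_planted) else character(0)
  idx <- 0L
  take <- function(n) {
    out <- planted[seq_len(n) + idx]
    idx <<- idx + n
    out
  }
  shared_ids <- take(cfg$n_shared_degs)
  f_ids <- take(cfg$n_female_unique_degs)
  m_ids <- take(cfg$n_male_unique_degs)
  int_ids <- take(cfg$n_interaction_genes)

  rsign <- function(n) sample(c(-1, 1), n, replace = TRUE)
  shared_dir <- rsign(length(shared_ids))
  f_dir <- rsign(length(f_ids))
  m_dir <- rsign(length(m_ids))
  # interaction genes: alternate which sex responds; the responding sex gets
  # a signed disease log2FC of magnitude interaction_log2fc, the other 0, so
  # the (male - female) interaction contrast equals +/- interaction_log2fc.
  int_sex <- rep(c("male", "female"), length.out = length(int_ids))
  int_sign <- rsign(length(int_ids))
  lfc_male <- ifelse(int_sex == "male", int_sign * cfg$interaction_log2fc, 0)
  lfc_female <- ifelse(int_sex == "female", int_sign * cfg$interaction_log2fc, 0)

  # per-gene disease log2FC by sex (zero effect when deg_log2fc == 0) -------
  eff_male <- eff_female <- setNames(numeric(cfg$n_genes), gene_ids)
  eff_male[shared_ids] <- shared_dir * cfg$deg_log2fc
  eff_female[shared_ids] <- shared_dir * cfg$deg_log2fc
  eff_female[f_ids] <- f_dir * cfg$deg_log2fc
  eff_male[m_ids] <- m_dir * cfg$deg_log2fc
  eff_male[int_ids] <- lfc_male
  eff_female[int_ids] <- lfc_female

  # baseline abundance on the CPM scale -------------------------------------
  base_log2 <- stats::rnorm(cfg$n_genes, mean = 0, sd = 2)
  w <- 2^base_log2
  base_cpm <- w / sum(w) * 1e6
  names(base_cpm) <- gene_ids

  # batch offsets: one per study per gene, additive on log2 CPM -------------
  batch <- matrix(stats::rnorm(cfg$n_studies * cfg$n_genes, 0, cfg$batch_sd),
                  nrow = cfg$n_studies,
                  dimnames = list(studies, gene_ids))
  if (cfg$batch_sd == 0) batch[] <- 0

  lib_sizes <- exp(stats::runif(n_samples,
                                log(cfg$lib_size_range[1]),
                                log(cfg$lib_size_range[2])))
  names(lib_sizes) <- meta$sample_id

  counts <- matrix(0L, nrow = cfg$n_genes, ncol = n_samples,
                   dimnames = list(gene_ids, meta$sample_id))
  marker_sex <- markers
  for (j in seq_len(n_samples)) {
    st <- meta$study[j]
    eff <- if (meta$condition[j] == "PS") {
      if (meta$sex[j] == "male") eff_male else eff_female
    } else {
      numeric(cfg$n_genes)
    }
    cpm_j <- base_cpm * 2^(batch[st, ] + eff)
    # markers override the baseline: sex-exclusive expression
    on_sex <- marker_sex == meta$sex[j]
    cpm_j[names(markers)] <- ifelse(on_sex,
                                    2^cfg$marker_logcpm_high,
                                    cfg$marker_noise_floor) *
      2^(batch[st, names(markers)])
    mu <- cpm_j / 1e6 * lib_sizes[j]
    counts[, j] <- stats::rnbinom(cfg$n_genes, mu = mu,
                                  size = 1 / cfg$dispersion)
  }
  storage.mode(counts) <- "integer"

  truth <- list(
    marker_genes = markers,
    shared_degs = data.frame(gene = shared_ids, direction = shared_dir,
                             log2fc = shared_dir * cfg$deg_log2fc,
                             stringsAsFactors = FALSE),
    female_unique_degs = data.frame(gene = f_ids, direction = f_dir,
                                    log2fc = f_dir * cfg$deg_log2fc,
                                    stringsAsFactors = FALSE),
    male_unique_degs = data.frame(gene = m_ids, direction = m_dir,
                                  log2fc = m_dir * cfg$deg_log2fc,
                                  stringsAsFactors = FALSE),
    interaction_genes = data.frame(gene = int_ids,
                                   lfc_male = lfc_male,
                                   lfc_female = lfc_female,
                                   stringsAsFactors = FALSE),
    sex = setNames(meta$sex, meta$sample_id),
    batch_offsets = batch,
    lib_sizes = lib_sizes,
    baseline_cpm = base_cpm,
    eff_male = eff_male,
    eff_female = eff_female
  )

  list(counts = counts, metadata = meta, truth = truth)
}

#' Generate cell-type enrichment scores with planted sex-specific shifts
#'
#' Emulates the input to the composition statistics: a cell-type by
#' sample score table (ordinal relative-abundance scores, as produced
#' by signature-based enrichment tools) across the four design groups.
#' Scores are Normal(group mean, `score_sd`) truncated at zero; the
#' disease effect for a given sex shifts the mean by
#' `shift_sd * score_sd`, so the planted standardized effect (Cohen's
#' D) equals `shift_sd`.
#'
#' @param n_cell_types number of cell types (rows).
#' @param group_sizes named integer vector over the four groups.
#' @param planted_effects optional data.frame with columns `cell_type`
#'   (integer row index or name), `sex` (`"male"`/`"female"`) and
#'   `shift_sd` (mean shift of PS vs Control in SD units). `NULL`
#'   plants nothing.
#' @param score_sd within-group standard deviation of the scores.
#' @param seed integer RNG seed.
#' @return List with `scores` (matrix), `metadata` (sample sheet) and
#'   `truth` (cell-type x sex matrix of planted standardized effects).
#' @export
generate_enrichment_scores <- function(n_cell_types = 64L,
                                       group_sizes = c(PS_male = 30L, PS_female = 30L,
                                                       Control_male = 30L, Control_female = 30L),
                                       planted_effects = NULL,
                                       score_sd = 0.05,
                                       seed = 1L) {
  grp <- group_levels()
  if (!all(grp %in% names(group_sizes))) {
    stopf("group_sizes must name the four groups %s", paste(grp, collapse = ", "))
  }
  if (score_sd < 0) stopf("score_sd must be >= 0, got %g", score_sd)
  group_sizes <- group_sizes[grp]

  with_seed(seed, {
    cts <- sprintf("celltype%02d", seq_len(n_cell_types))
    planted <- matrix(0, nrow = n_cell_types, ncol = 2,
                      dimnames = list(cts, c("male", "female")))
    if (!is.null(planted_effects)) {
      for (k in seq_len(nrow(planted_effects))) {
        ct <- planted_effects$cell_type[k]
        ct <- if (is.numeric(ct)) cts[ct] else as.character(ct)
        planted[ct, planted_effects$sex[k]] <- planted_effects$shift_sd[k]
      }
    }

    meta <- do.call(rbind, lapply(grp, function(g) {
      n <- group_sizes[[g]]
      if (n == 0L) return(NULL)
      data.frame(group = g, stringsAsFactors = FALSE)[rep(1, n), , drop = FALSE]
    }))
    rownames(meta) <- NULL
    meta$condition <- ifelse(startsWith(meta$group, "PS"), "PS", "Control")
    meta$sex <- ifelse(endsWith(meta$group, "female"), "female", "male")
    meta$sample_id <- sprintf("ES%03d_%s", seq_len(nrow(meta)), meta$group)
    meta <- meta[, c("sample_id", "condition", "sex", "group")]

    baseline <- stats::runif(n_cell_types, 0.1, 0.6)
    scores <- matrix(0, nrow = n_cell_types, ncol = nrow(meta),
                     dimnames = list(cts, meta$sample_id))
    for (j in seq_len(nrow(meta))) {
      shift <- if (meta$condition[j] == "PS") planted[, meta$sex[j]] else 0
      mu <- baseline + shift * score_sd
      scores[, j] <- pmax(0, stats::rnorm(n_cell_types, mu, score_sd))
    }

    list(scores = scores, metadata = meta, truth = planted)
  })
}
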