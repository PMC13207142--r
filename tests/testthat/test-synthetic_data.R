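test_that("identical seed and config give identical output", {
  cfg <- tiny_sim_config(seed = 11L)
  a <- generate_counts(cfg)
  b <- generate_counts(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$truth, b$truth)
  c <- generate_counts(tiny_sim_config(seed = 12L))
  expect_false(identical(a$counts, c$counts))
})

test_that("planted gene sets are disjoint and never touch the markers", {
  sim <- generate_counts(tiny_sim_config(seed = 21L))
  tr <- sim$truth
  sets <- list(tr$shared_degs$gene, tr$female_unique_degs$gene,
               tr$male_unique_degs$gene, tr$interaction_genes$gene)
  all_ids <- unlist(sets)
  expect_equal(anyDuplicated(all_ids), 0L)
  expect_length(intersect(all_ids, names(sex_marker_genes())), 0)
  expect_true(all(abs(tr$shared_degs$log2fc) == 2))
  expect_true(all(sim$counts >= 0))
  expect_type(sim$counts[1, 1], "integer")
})

test_that("metadata group counts follow the configured design, including uneven matrices", {
  sizes <- matrix(c(3L, 5L, 2L, 4L,
                    1L, 2L, 6L, 0L), nrow = 2, byrow = TRUE,
                  dimnames = list(NULL, c("PS_male", "PS_female",
                                          "Control_male", "Control_female")))
  sim <- generate_counts(tiny_sim_config(
    seed = 31L, n_studies = 2L, samples_per_group_per_study = sizes))
  tab <- table(sim$metadata$study, sim$metadata$group)
  expect_equal(unname(tab["study01", c("PS_male", "PS_female",
                                       "Control_male", "Control_female")]),
               c(3L, 5L, 2L, 4L))
  expect_equal(unname(tab["study02", "Control_female"]), 0L)
})

test_that("zero planted effect means no systematic disease difference", {
  cfg <- tiny_sim_config(seed = 41L, deg_log2fc = 0, interaction_log2fc = 0,
                         batch_sd = 0)
  sim <- generate_counts(cfg)
  expect_true(all(sim$truth$eff_male == 0))
  expect_true(all(sim$truth$eff_female == 0))
  # PS vs Control mean CPM ratio on well-expressed genes: noise only
  cpm <- t(t(sim$counts) / colSums(sim$counts)) * 1e6
  expressed <- sim$truth$baseline_cpm > 50
  expressed[names(sex_marker_genes())] <- FALSE
  ps <- rowMeans(cpm[expressed, sim$metadata$condition == "PS"])
  ct <- rowMeans(cpm[expressed, sim$metadata$condition == "Control"])
  lfc <- log2(ps / ct)
  expect_lt(abs(mean(lfc)), 3 * stats::sd(lfc) / sqrt(length(lfc)))
})

test_that("per-study expression shifts track the stored batch offsets", {
  cfg <- tiny_sim_config(seed = 51L, n_studies = 2L, batch_sd = 1.0,
                         deg_log2fc = 0, interaction_log2fc = 0,
                         n_shared_degs = 0L, n_female_unique_degs = 0L,
                         n_male_unique_degs = 0L, n_interaction_genes = 0L)
  sim <- generate_counts(cfg)
  lc <- logcpm(sim$counts)
  s1 <- sim$metadata$study == "study01"

  # oracle: expected measured CPM recomputed from the stored baseline
  # and batch offsets (marker rows depend on sex, handled per sample)
  markers <- sex_marker_genes()
  expected_cpm <- vapply(seq_len(nrow(sim$metadata)), function(j) {
    st <- sim$metadata$study[j]
    cpm <- sim$truth$baseline_cpm * 2^sim$truth$batch_offsets[st, ]
    on_sex <- markers == sim$metadata$sex[j]
    cpm[names(markers)] <- ifelse(on_sex, 2^cfg$marker_logcpm_high,
                                  cfg$marker_noise_floor) *
      2^sim$truth$batch_offsets[st, names(markers)]
    cpm / sum(cpm) * 1e6
  }, numeric(cfg$n_genes))
  d_true <- rowMeans(log2(expected_cpm[, s1])) -
    rowMeans(log2(expected_cpm[, !s1]))

  genes <- setdiff(names(which(sim$truth$baseline_cpm > 50)),
                   names(markers))
  d_hat <- rowMeans(lc[genes, s1]) - rowMeans(lc[genes, !s1])
  resid <- d_hat - d_true[match(genes, rownames(sim$counts))]
  # mean discrepancy across genes within 3 SE of zero
  expect_lt(abs(mean(resid)), 3 * stats::sd(resid) / sqrt(length(resid)))
  # and the per-study offsets dominate the observed shifts
  expect_gt(stats::cor(d_hat,
                       sim$truth$batch_offsets["study01", genes] -
                         sim$truth$batch_offsets["study02", genes]), 0.95)
})

test_that("planted shared-DEG effects are calibrated to deg_log2fc", {
  cfg <- tiny_sim_config(seed = 61L, n_studies = 1L, n_genes = 1000L,
                         n_shared_degs = 200L, n_female_unique_degs = 0L,
                         n_male_unique_degs = 0L, n_interaction_genes = 0L,
                         batch_sd = 0,
                         samples_per_group_per_study = c(
                           PS_male = 10L, PS_female = 10L,
                           Control_male = 10L, Control_female = 10L))
  sim <- generate_counts(cfg)
  cpm <- t(t(sim$counts) / colSums(sim$counts)) * 1e6
  tr <- sim$truth$shared_degs
  ps <- rowMeans(cpm[tr$gene, sim$metadata$condition == "PS"])
  ct <- rowMeans(cpm[tr$gene, sim$metadata$condition == "Control"])
  lfc_hat <- log2(ps / ct) * tr$direction
  se <- stats::sd(lfc_hat) / sqrt(nrow(tr))
  expect_lt(abs(mean(lfc_hat) - cfg$deg_log2fc), 3 * se)
})

test_that("sex markers are exclusive and linearly separable at default settings", {
  sim <- generate_counts(tiny_sim_config(seed = 71L))
  lc <- logcpm(sim$counts)
  female <- sim$metadata$sex == "female"
  expect_gt(min(lc["XIST", female]), max(lc["XIST", !female]))
  for (g in c("EIF1AY", "KDM5D", "UTY", "DDX3Y", "RPS4Y1")) {
    expect_gt(min(lc[g, !female]), max(lc[g, female]))
  }
})

test_that("invalid configurations are rejected with informative errors", {
  expect_error(tiny_sim_config(dispersion = 0), "dispersion")
  expect_error(tiny_sim_config(n_genes = 40L), "planted")
  expect_error(tiny_sim_config(batch_sd = -1), "batch_sd")
  expect_error(
    tiny_sim_config(samples_per_group_per_study = c(PS_male = 3L)),
    "four groups")
})

test_that("enrichment-score generator plants the requested standardized effects", {
  es <- generate_enrichment_scores(
    n_cell_types = 64L,
    group_sizes = c(PS_male = 30L, PS_female = 30L,
                    Control_male = 30L, Control_female = 30L),
    planted_effects = data.frame(cell_type = 5L, sex = "male", shift_sd = 1),
    seed = 81L)
  expect_equal(nrow(es$scores), 64L)
  expect_equal(ncol(es$scores), 120L)
  expect_true(all(es$scores >= 0))
  expect_equal(unname(es$truth[5, "male"]), 1)
  expect_equal(sum(es$truth != 0), 1L)

  # empirical Cohen's D close to the planted standardized effect
  x <- es$scores[5, ]
  m <- es$metadata
  dm <- cohens_d(x[m$group == "PS_male"], x[m$group == "Control_male"])
  df_ <- cohens_d(x[m$group == "PS_female"], x[m$group == "Control_female"])
  expect_lt(abs(dm$d - 1), 3 * sqrt(dm$var_d))
  expect_lt(abs(df_$d - 0), 3 * sqrt(df_$var_d))

  expect_error(generate_enrichment_scores(score_sd = -0.1, seed = 1), "score_sd")
})

test_that("enrichment-score generation is deterministic given the seed", {
  a <- generate_enrichment_scores(n_cell_types = 8L, seed = 91L)
  b <- generate_enrichment_scores(n_cell_types = 8L, seed = 91L)
  expect_identical(a$scores, b$scores)
})
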