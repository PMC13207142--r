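test_that("design has group means plus study blocks and is rank checked", {
  groups <- rep(group_levels(), each = 2)
  meta <- rbind(meta_for_groups(groups, study = "study01",
                                ids = sprintf("a%02d", 1:8)),
                meta_for_groups(groups, study = "study02",
                                ids = sprintf("b%02d", 1:8)))
  X <- build_design(meta)
  expect_equal(dim(X), c(16L, 5L))
  expect_equal(qr(X)$rank, 5L)
  expect_true(all(rowSums(X[, group_levels()]) == 1))
  expect_equal(attr(X, "study_cols"), "study_study02")

  # single study: blocking is vacuous
  X1 <- build_design(meta[meta$study == "study01", ])
  expect_equal(ncol(X1), 4L)

  # a study holding only PS_male is still estimable when PS_male also
  # appears elsewhere (rank oracle: explicit qr)
  meta3 <- rbind(meta_for_groups(groups, study = "study01",
                                 ids = sprintf("c%02d", 1:8)),
                 meta_for_groups(rep("PS_male", 3), study = "study02",
                                 ids = sprintf("d%02d", 1:3)))
  X3 <- build_design(meta3)
  expect_equal(qr(X3)$rank, ncol(X3))

  # full confounding: a group appearing only in its own study
  meta4 <- rbind(meta_for_groups(rep(c("PS_female", "Control_male",
                                       "Control_female"), 2), study = "study01",
                                 ids = sprintf("e%02d", 1:6)),
                 meta_for_groups(rep("PS_male", 3), study = "study02",
                                 ids = sprintf("f%02d", 1:3)))
  expect_error(build_design(meta4), "rank deficient")

  meta_unk <- meta
  meta_unk$sex[1] <- "unknown"
  meta_unk$group[1] <- NA
  expect_error(build_design(meta_unk), "known sex")
})

test_that("weighted least squares reduces to group means and honors weights", {
  groups <- rep(c("PS_male", "Control_male"), each = 4)
  meta <- meta_for_groups(groups)
  X <- build_design(meta)[, c("PS_male", "Control_male")]
  set.seed(601)
  y <- matrix(rnorm(12 * 8), nrow = 12,
              dimnames = list(sprintf("g%02d", 1:12), meta$sample_id))
  fit <- fit_weighted_lm(y, X)
  expect_equal(unname(fit$coefficients[, "PS_male"]),
               unname(rowMeans(y[, 1:4])), tolerance = 1e-12)
  expect_equal(unname(fit$df.residual), rep(6, 12))

  # replication trick: weight 2 on one sample == including it twice
  w <- matrix(1, 12, 8); w[, 1] <- 2
  fit_w <- limma::lmFit(y, X, weights = w)
  y_dup <- cbind(y[, 1, drop = FALSE], y)
  colnames(y_dup) <- c("dup", colnames(y))
  X_dup <- rbind(X[1, , drop = FALSE], X)
  fit_dup <- limma::lmFit(y_dup, X_dup)
  expect_equal(unname(fit_w$coefficients), unname(fit_dup$coefficients),
               tolerance = 1e-10)

  # noiseless data generated from known coefficients is recovered exactly
  beta <- cbind(PS_male = 1:12, Control_male = 12:1)
  y0 <- beta %*% t(X)
  dimnames(y0) <- dimnames(y)
  fit0 <- fit_weighted_lm(y0, X)
  expect_equal(unname(fit0$coefficients), unname(beta), tolerance = 1e-10)

  expect_error(fit_weighted_lm(y[, c(1, 5)], X[c(1, 5), ]), "residual degrees")
})

test_that("moderated variances follow the posterior formula and the equal-variance branch", {
  set.seed(602)
  y <- matrix(rnorm(2000 * 10), nrow = 2000)
  rownames(y) <- sprintf("g%04d", seq_len(2000))
  colnames(y) <- sprintf("s%02d", 1:10)
  X <- cbind(A = rep(1:0, each = 5), B = rep(0:1, each = 5))
  eb <- ebayes_moderate(fit_weighted_lm(y, X))
  d0 <- eb$df.prior; s02 <- eb$s2.prior; dg <- eb$df.residual
  expect_equal(unname(eb$s2.post),
               unname((d0 * s02 + dg * eb$sigma^2) / (d0 + dg)),
               tolerance = 1e-9)

  # all residual variances identical -> infinite prior df, posterior = prior
  yc <- y
  yc[] <- rep(c(-1, 1), length.out = length(yc))  # same spread every gene
  ebc <- ebayes_moderate(fit_weighted_lm(yc, X))
  expect_true(is.infinite(ebc$df.prior))
  expect_equal(unname(ebc$s2.post), rep(ebc$s2.prior, nrow(yc)), tolerance = 1e-9)

  expect_error(ebayes_moderate(fit_weighted_lm(y[1:5, ], X)), "at least 10 genes")
})

test_that("contrasts are linear in coefficients and exclude study columns", {
  groups <- rep(group_levels(), each = 4)
  meta <- rbind(meta_for_groups(groups, study = "study01",
                                ids = sprintf("a%02d", 1:16)),
                meta_for_groups(groups, study = "study02",
                                ids = sprintf("b%02d", 1:16)))
  X <- build_design(meta)
  contr <- make_group_contrasts(X)
  expect_equal(unname(contr[, "interaction"]),
               unname(contr[, "male"] - contr[, "female"]))
  expect_true(all(contr["study_study02", ] == 0))

  set.seed(603)
  y <- matrix(rnorm(50 * 32), nrow = 50,
              dimnames = list(sprintf("g%02d", 1:50), meta$sample_id))
  fit <- fit_weighted_lm(y, X)
  fit$design <- X
  tabs <- apply_contrasts(fit, contr)
  expect_equal(tabs$interaction$logFC, tabs$male$logFC - tabs$female$logFC,
               tolerance = 1e-12)

  # noiseless group-mean data: contrast recovers the exact difference
  beta <- cbind(PS_male = rep(3, 50), PS_female = rep(1, 50),
                Control_male = rep(1, 50), Control_female = rep(1, 50),
                study_study02 = rep(0.7, 50))
  y0 <- beta %*% t(X) + 1e-4 * matrix(rnorm(50 * 32), nrow = 50)
  dimnames(y0) <- dimnames(y)
  fit0 <- fit_weighted_lm(y0, X)
  fit0$design <- X
  tabs0 <- apply_contrasts(fit0, contr)
  expect_equal(tabs0$male$logFC, rep(2, 50), tolerance = 1e-2)
  expect_equal(tabs0$interaction$logFC, rep(2, 50), tolerance = 1e-2)

  bad <- contr
  bad["study_study02", "male"] <- 1
  expect_error(apply_contrasts(fit, bad), "study blocking")
})

test_that("BH adjustment matches the step-up oracle and preserves order", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")

  set.seed(604)
  for (n in c(1, 2, 5, 8)) {
    for (rep_ in 1:25) {
      p <- round(runif(n), 3)
      expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
    }
  }
  p <- runif(8)
  expect_true(all(bh_adjust(p) >= p))
})

test_that("DEG calling uses strict thresholds on both criteria", {
  tab <- data.frame(gene = c("a", "b", "c", "d"),
                    logFC = c(1.0, 1.2, -3, 1.5),
                    t = 0, p = 0,
                    adj_p = c(0.001, 0.01, 0.2, 0.05))
  out <- call_degs(tab)
  expect_equal(out$deg, c(FALSE, TRUE, FALSE, FALSE))  # 1.0 and 0.05 both excluded
  expect_equal(out$direction, c("n.s.", "Up", "n.s.", "n.s."))
})

test_that("DEG partition counts, labels and consistency flags are correct", {
  mk <- function(genes, lfc, adj) {
    call_degs(data.frame(gene = genes, logFC = lfc, t = 0, p = 0, adj_p = adj))
  }
  f <- mk(c("a", "b", "c"), c(2, -2, 1.5), c(0.01, 0.01, 0.5))
  m <- mk(c("a", "b", "c"), c(2, 2, -1.6), c(0.01, 0.01, 0.01))
  out <- partition_degs(f, m)
  expect_equal(unname(out$counts), c(0L, 1L, 2L))  # female_only, male_only, overlap
  p <- out$partition
  expect_equal(p$label[p$gene == "a"], "Up (M, F)")
  expect_equal(p$label[p$gene == "b"], "Up (M) Down (F)")
  expect_equal(p$label[p$gene == "c"], "Down (M)")
  expect_true(p$consistent[p$gene == "a"])
  expect_false(p$consistent[p$gene == "b"])

  disj <- partition_degs(mk("a", 2, 0.01), mk("b", 2, 0.01))
  expect_equal(unname(disj$counts), c(1L, 1L, 0L))
})

test_that("planted DEGs and interaction genes are recovered by the full DE run", {
  cfg <- tiny_sim_config(seed = 701L, n_studies = 2L, n_genes = 1200L,
                         n_shared_degs = 50L, n_female_unique_degs = 10L,
                         n_male_unique_degs = 5L, n_interaction_genes = 6L)
  sim <- generate_counts(cfg)
  de <- run_de(sim$counts, sim$metadata)
  tr <- sim$truth

  shared_hit <- mean(tr$shared_degs$gene %in% intersect(de$degs$female, de$degs$male))
  expect_gt(shared_hit, 0.8)

  int_called <- de$tables$interaction$gene[de$tables$interaction$deg]
  expect_gt(mean(tr$interaction_genes$gene %in% int_called), 0.8)

  # interaction direction matches the planted per-sex difference
  tab <- de$tables$interaction
  planted_diff <- tr$interaction_genes$lfc_male - tr$interaction_genes$lfc_female
  est <- tab$logFC[match(tr$interaction_genes$gene, tab$gene)]
  expect_true(all(sign(est) == sign(planted_diff)))
  expect_equal(est, planted_diff, tolerance = 0.35)
})

test_that("balanced subsampling is an identity on balanced data and deterministic", {
  cfg <- tiny_sim_config(seed = 801L, n_genes = 500L, n_shared_degs = 20L,
                         n_female_unique_degs = 5L, n_male_unique_degs = 5L,
                         n_interaction_genes = 0L)
  sim <- generate_counts(cfg)
  bs <- balanced_sensitivity(sim$counts, sim$metadata, seed = 1L)
  expect_setequal(bs$kept_samples, sim$metadata$sample_id)
  expect_identical(bs$jaccard, c(female = 1, male = 1, interaction = 1))

  bs2 <- balanced_sensitivity(sim$counts, sim$metadata, seed = 1L)
  expect_identical(bs$kept_samples, bs2$kept_samples)
})

test_that("imbalanced data still recovers the full-run DEG sets after balancing", {
  cfg <- tiny_sim_config(
    seed = 901L, n_studies = 2L, n_genes = 800L, n_shared_degs = 40L,
    n_female_unique_degs = 5L, n_male_unique_degs = 5L,
    n_interaction_genes = 0L,
    samples_per_group_per_study = c(PS_male = 12L, PS_female = 6L,
                                    Control_male = 12L, Control_female = 6L))
  sim <- generate_counts(cfg)
  bs <- balanced_sensitivity(sim$counts, sim$metadata, seed = 2L)
  kept <- sim$metadata[sim$metadata$sample_id %in% bs$kept_samples, ]
  for (cond in c("PS", "Control")) {
    sub <- kept[kept$condition == cond, ]
    expect_equal(sum(sub$sex == "male"), sum(sub$sex == "female"))
  }
  expect_gte(bs$jaccard[["female"]], 0.8)
  expect_gte(bs$jaccard[["male"]], 0.8)

  one_sex <- sim$metadata[sim$metadata$sex == "male", ]
  expect_error(balanced_sensitivity(sim$counts[, one_sex$sample_id], one_sex,
                                    seed = 1L), "single sex")
})
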