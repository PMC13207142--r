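# Sex-stratified statistics on cell-type enrichment scores. The
# scores are ordinal relative-abundance measures, so group
# distributions are compared non-parametrically (Kruskal-Wallis with
# Dunn's post hoc), and the size of the disease response per sex is
# quantified by Cohen's D with a z-test on the male-female difference
# of effect sizes.

#' Kruskal-Wallis test for one cell type
#'
#' Tie-corrected H statistic with a chi-square p-value on k - 1 df.
#' The degenerate all-values-equal case (which the textbook formula
#' leaves 0/0) is defined as no evidence of difference: H = 0, p = 1.
#'
#' @param x scores.
#' @param g group labels (at least two non-empty groups).
#' @return List with `H`, `p` and `df`.
#' @export
kruskal_wallis <- function(x, g) {
  g <- droplevels(factor(g))
  if (nlevels(g) < 2L) stopf("Kruskal-Wallis needs at least two groups")
  if (length(unique(x)) == 1L) {
    return(list(H = 0, p = 1, df = nlevels(g) - 1L))
  }
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), p = kt$p.value, df = unname(kt$parameter))
}

#' Dunn's post hoc pairwise comparisons
#'
#' Pairwise z-statistics on the mean ranks of the shared (all-group)
#' ranking,
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T) * (1/n_i + 1/n_j))`
#' with the tie correction `T = sum(t^3 - t) / (12 (N - 1))`,
#' two-sided normal p-values, and BH adjustment across the reported
#' pairs. With exactly two groups the statistic reduces to the
#' normal-approximation rank-sum z.
#'
#' @param x scores.
#' @param g group labels.
#' @param comparisons optional character vector of `"A-B"` pairs to
#'   report (default: all pairs). Adjustment is across the reported
#'   pairs only.
#' @param p_adjust_method multiplicity adjustment (default BH).
#' @return data.frame with `group1`, `group2`, `z`, `p`, `p_adj`.
#' @export
dunn_posthoc <- function(x, g, comparisons = NULL, p_adjust_method = "BH") {
  g <- droplevels(factor(g))
  if (nlevels(g) < 2L) stopf("Dunn's test needs at least two groups")
  n_g <- table(g)
  if (any(n_g == 0)) stopf("empty group(s): %s", paste(names(n_g)[n_g == 0], collapse = ", "))
  N <- length(x)
  r <- rank(x)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  mean_rank <- tapply(r, g, mean)

  pairs <- utils::combn(levels(g), 2)
  lab <- paste(pairs[1, ], pairs[2, ], sep = "-")
  if (!is.null(comparisons)) {
    sel <- lab %in% comparisons |
      paste(pairs[2, ], pairs[1, ], sep = "-") %in% comparisons
    if (!any(sel)) stopf("none of the requested comparisons match the groups")
    pairs <- pairs[, sel, drop = FALSE]
    lab <- lab[sel]
  }
  z <- vapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    (mean_rank[[i]] - mean_rank[[j]]) /
      sqrt((N * (N + 1) / 12 - tie_term) * (1 / n_g[[i]] + 1 / n_g[[j]]))
  }, numeric(1))
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z, p = p,
             p_adj = stats::p.adjust(p, method = p_adjust_method),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Cohen's D with its large-sample variance
#'
#' Pooled-SD standardized mean difference
#' `d = (mean(x1) - mean(x0)) / s_pooled` with
#' `s_pooled^2 = ((n1-1) s1^2 + (n0-1) s0^2) / (n1 + n0 - 2)`, and the
#' large-sample variance approximation
#' `var_d = (n1+n0)/(n1*n0) + d^2 / (2 (n1+n0))`. No small-sample
#' (Hedges) correction is applied.
#'
#' @param x_disease,x_control score vectors (each of length >= 2).
#' @return List with `d`, `var_d`, `n1`, `n0`.
#' @export
cohens_d <- function(x_disease, x_control) {
  n1 <- length(x_disease)
  n0 <- length(x_control)
  if (n1 < 2L || n0 < 2L) stopf("Cohen's D needs at least 2 observations per group")
  sp2 <- ((n1 - 1) * stats::var(x_disease) + (n0 - 1) * stats::var(x_control)) /
    (n1 + n0 - 2)
  if (sp2 <= 0) stopf("pooled variance is zero; Cohen's D is undefined")
  d <- (mean(x_disease) - mean(x_control)) / sqrt(sp2)
  var_d <- (n1 + n0) / (n1 * n0) + d^2 / (2 * (n1 + n0))
  list(d = d, var_d = var_d, n1 = n1, n0 = n0)
}

#' z-test on the male-female difference in effect sizes
#'
#' `z = (d_male - d_female) / sqrt(var_d_male + var_d_female)` with a
#' two-sided standard-normal p-value: does the disease effect size for
#' a cell type differ between the sexes?
#'
#' @param d_male,var_d_male male Cohen's D and its variance.
#' @param d_female,var_d_female female Cohen's D and its variance.
#' @return List with `z` and `p`.
#' @export
effect_size_sex_test <- function(d_male, var_d_male, d_female, var_d_female) {
  if (var_d_male <= 0 || var_d_female <= 0) stopf("variances must be positive")
  z <- (d_male - d_female) / sqrt(var_d_male + var_d_female)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' FDR correction across cell types
#'
#' BH adjustment of the sex-difference p-values across cell types
#' (shared step-up implementation with the DEG pipeline); significance
#' is declared at `fdr < 0.05`.
#'
#' @param rows data.frame with a `p` column.
#' @param alpha significance level on the FDR scale.
#' @return `rows` with `fdr` and `significant` columns added.
#' @export
composition_fdr <- function(rows, alpha = 0.05) {
  rows$fdr <- bh_adjust(rows$p)
  rows$significant <- rows$fdr < alpha
  rows
}

#' Sex-stratified composition statistics for a score table
#'
#' Per cell type: four-group Kruskal-Wallis with Dunn's post hoc
#' pairwise comparisons, per-sex Cohen's D of psoriasis vs control,
#' the z-test on the male-female difference of effect sizes, and BH
#' FDR across cell types.
#'
#' @param scores cell-type x sample score matrix.
#' @param meta aligned sample metadata with `group`, `condition`, `sex`.
#' @param comparisons optional Dunn pair subset (see [dunn_posthoc()]).
#' @param alpha FDR significance level.
#' @return List with `effects` (per-cell-type d_F, d_M, variances, z,
#'   p, fdr), `kruskal` (per-cell-type H and p) and `dunn` (long
#'   data.frame over cell types and pairs).
#' @export
composition_stats <- function(scores, meta, comparisons = NULL, alpha = 0.05) {
  if (!all(colnames(scores) == meta$sample_id)) {
    meta <- meta[match(colnames(scores), meta$sample_id), , drop = FALSE]
    if (any(is.na(meta$sample_id))) stopf("metadata does not cover all score samples")
  }
  grp <- factor(meta$group, levels = group_levels())

  kw <- do.call(rbind, lapply(rownames(scores), function(ct) {
    res <- kruskal_wallis(scores[ct, ], grp)
    data.frame(cell_type = ct, H = res$H, kw_p = res$p, stringsAsFactors = FALSE)
  }))

  dunn <- do.call(rbind, lapply(rownames(scores), function(ct) {
    cbind(cell_type = ct,
          dunn_posthoc(scores[ct, ], grp, comparisons = comparisons))
  }))

  eff <- do.call(rbind, lapply(rownames(scores), function(ct) {
    x <- scores[ct, ]
    dm <- cohens_d(x[meta$group == "PS_male"], x[meta$group == "Control_male"])
    df_ <- cohens_d(x[meta$group == "PS_female"], x[meta$group == "Control_female"])
    zt <- effect_size_sex_test(dm$d, dm$var_d, df_$d, df_$var_d)
    data.frame(cell_type = ct,
               d_female = df_$d, var_d_female = df_$var_d,
               d_male = dm$d, var_d_male = dm$var_d,
               z = zt$z, p = zt$p, stringsAsFactors = FALSE)
  }))
  eff <- composition_fdr(eff, alpha = alpha)

  list(effects = eff, kruskal = kw, dunn = dunn)
}
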