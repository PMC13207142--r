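---
title: "Methods: sex-stratified multi-study RNA-seq analysis with sexstrat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sex-stratified multi-study RNA-seq analysis with sexstrat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`sexstrat` implements a sex-stratified meta-analysis of bulk RNA-seq
counts pooled across studies: sex inference from marker-gene
expression, quality filtering, TMM/voom normalization, study-blocked
differential expression with a sex-by-disease interaction contrast,
batch-corrected multidimensional scaling, and sex-stratified
cell-composition statistics. This vignette records the statistical
model behind each stage, the tunable parameters and their defaults,
the numerical choices, and what the accompanying simulator does and
does not emulate.

```{r setup}
library(sexstrat)
```

## The design and its assumptions

Samples are labeled by one of four groups — `PS_male`, `PS_female`,
`Control_male`, `Control_female` — and by study of origin. All
modeling assumes:

* counts are gene-level, non-negative integers from independent
  samples (no repeated measures, no paired designs);
* between-study variation is a gene-wise *additive shift on the log
  scale* (equivalently multiplicative on counts), shared by all
  samples of a study — exactly what a linear blocking term or the
  protected linear batch correction can absorb;
* within a group, counts are exchangeable; after voom's
  precision-weighting, gene-wise weighted least squares with normal
  theory is a good approximation.

Study is modeled as a *fixed* blocking factor: the design matrix is a
group-means parameterization (one indicator per group, no intercept)
plus `n_studies - 1` study indicators. The group-means form makes the
three contrasts of interest literal group differences:

```
female      = PS_female - Control_female
male        = PS_male   - Control_male
interaction = male - female
```

A nonzero interaction means the disease response differs by sex. Note
that a gene responding in only one sex is itself an interaction gene;
the interaction contrast does not distinguish "female-only response"
from "opposite responses of half the size in each sex".

## Sex inference from six marker genes

Biological sex leaves an unambiguous expression signature: *XIST* is
expressed essentially only in female samples, and *EIF1AY*, *KDM5D*,
*UTY*, *DDX3Y*, *RPS4Y1* essentially only in males. The classifier is
an L1-penalized logistic regression of sex on the six logCPM features,
female coded as the positive class.

Choices that matter, with defaults:

* **Features** are `log2((count + 0.5) / (library + 1) * 1e6)` — the
  same pseudo-count logCPM used by the voom transformation, so the
  classifier and the linear model see consistently defined
  expression values.
* **Solver**: coordinate descent over an IRLS quadratic approximation
  (the standard GLM lasso scheme), intercept unpenalized, features
  standardized to unit (1/n) variance during fitting and coefficients
  returned on the original scale. At `lambda = 0` the solver reduces
  to plain IRLS and reproduces `glm()` coefficients to well below
  1e-6 (tested).
* **Penalty path**: 100 values log-spaced from `lambda_max` (the
  smallest penalty with all-zero coefficients, computed in closed
  form) down by a factor of 1e-4.
* **Cross-validation**: 10-fold, folds stratified by class and
  deterministic given the seed; the selection criterion is mean
  held-out binomial deviance (a smoother criterion than
  misclassification on near-separable data, where entire stretches of
  the path have zero errors).
* **Decision rule**: female iff P(female) > 0.5, strictly; a
  probability of exactly 0.5 is called male. The threshold is stored
  in the model object and fixed at training time.

`infer_missing_sex()` only ever fills samples whose metadata sex is
the explicit string `"unknown"`; reported labels are never
overwritten, and provenance is kept in a `sex_source` column.

## Filters and normalization

* **Library-size filter** (applied first, before any gene filter):
  keep samples with total counts strictly greater than 1e7.
* **Low-expression filter**: the standard `filterByExpr` rule — CPM
  above the cutoff implied by `min_count = 10` at the median library
  size in at least as many samples as the smallest group, and total
  count at least `min_total_count = 15`.
* **TMM** factors with the conventional trims (30% on log-ratios, 5%
  on average expression), rescaled to geometric mean one. The test
  suite holds the implementation to a brute-force re-derivation of
  the doubly trimmed, inverse-variance-weighted mean at 1e-8. Exact
  invariance to rescaling one library does not hold (the asymptotic
  binomial weights shift slightly with depth); the tests assert
  invariance to 2%.
* **voom**: per-gene linear fits on logCPM, a lowess trend (span 0.5,
  configurable) of sqrt residual SD versus average log2 count, and
  observation weights equal to predicted SD^-4. The voom design is
  the *study-blocked* design, not a group-only design: precision
  weights should reflect the residual variance around the model that
  will actually be fitted.

## Moderation, DEG calling and partitioning

Residual variances are shrunk by empirical Bayes: the prior
`(d0, s0^2)` is estimated by moment matching on the log variances
(digamma/trigamma inversion), the posterior variance is
`(d0 s0^2 + d_g s_g^2) / (d0 + d_g)`, and moderated t statistics have
`d0 + d_g` degrees of freedom. When every gene has the same residual
variance the prior degrees of freedom are infinite and all posterior
variances collapse to the prior — handled, and tested.

A gene is a DEG iff `|log2FC| > 1` **and** BH-adjusted `p < 0.05`,
both strict, in every contrast including the interaction (the same
rule is deliberately shared). The female/male DEG sets are partitioned
into female-only / male-only / overlap; overlap genes carry a
directional-consistency flag. Consistency is *reported, not filtered
on* — discordant overlap genes remain in the overlap set with a
label such as `"Up (M) Down (F)"`.

Because pooled public cohorts are usually male-skewed,
`balanced_sensitivity()` subsamples without replacement to equal
male/female numbers within each condition (drawing across studies
where possible), re-runs the full DE pipeline and reports per-contrast
Jaccard overlap with the full-data run.

## MDS after batch removal

For visualization only, the study component is removed from logCPM by
per-gene linear regression with the group indicators protected, and
classical MDS (double centering + eigendecomposition of Euclidean
distances) is run on the 500 most variable genes. Both the gene subset
and the distance are choices: 500 top-variance genes with Euclidean
distance is conventional and cheap; a pairwise-logFC variant (as used
by some expression tools) would emphasize large fold changes more and
can be substituted upstream of `mds_embed()`. Batch removal is
idempotent and never enters the inferential pipeline — the linear
model handles study by blocking instead, which keeps degrees of
freedom honest.

## Cell-composition statistics

Cell-type enrichment scores are *ordinal relative-abundance* measures,
not proportions, so:

* group distributions are compared per cell type with the
  tie-corrected Kruskal–Wallis test (the all-values-equal degenerate
  case is defined as H = 0, p = 1), followed by Dunn's post hoc
  pairwise z tests on the shared ranking, BH-adjusted across the
  reported pairs;
* scores are analyzed as given — no logit or arcsine transform, which
  would pretend the scores were proportions;
* effect sizes use pooled-SD Cohen's D without the Hedges small-sample
  correction, with the large-sample variance
  `(n1+n2)/(n1 n2) + d^2/(2(n1+n2))`;
* the sex difference in disease response is tested per cell type by
  `z = (d_M - d_F) / sqrt(Var d_M + Var d_F)` against the standard
  normal, BH-corrected across cell types at FDR < 0.05.

**Power is a real limitation here.** For a 1-SD male-only shift with
30 samples per group, Var(d) is about 0.075 for males and 0.067 for
females, so E[z] is roughly 1/sqrt(0.142) = 2.66 with unit spread.
That gives about 76% power for a single *uncorrected* two-sided test —
and far less (roughly a quarter) once BH across 64 cell types requires
p near 0.05/64. Sex differences in composition of this magnitude and
sample size are therefore detectable only sporadically; reliable
detection needs either larger cohorts, fewer candidate cell types, or
standardized differences well above 1. The validation suite measures
exactly this detection rate and documents it rather than hiding it.

## The simulator: what it emulates, and what it does not

`generate_counts()` draws counts from a negative binomial with
variance `mu + phi mu^2` and a single common dispersion `phi` (default
0.1, a typical bulk RNA-seq value). Expected CPM is per-gene baseline
abundance (log-normal across genes, normalized to a million) times a
per-study per-gene batch multiplier `2^N(0, batch_sd)` times the
planted group-effect multiplier; library sizes are log-uniform over
`[8e6, 3e7]` so that the 10-million library filter actually removes
some samples. Defaults plant 100 shared DEGs, 30 female-unique, 30
male-unique and 10 interaction genes at |log2FC| = 2 across 3 studies
of 8 samples per group — a small multi-study cohort with batch effects
comparable to the biological signal (`batch_sd = 0.5`). The six marker
genes are simulated under their real symbols: logCPM about 8 in the
expressing sex, and expected CPM equal to `marker_noise_floor`
(default 0.1) in the other, which keeps the realized off-sex logCPM at
or below about 0.1.

Deliberately **not** modeled: gene lengths and GC content (RPKM is
exercised with user-supplied lengths), gene–gene correlation,
per-gene dispersion variation, outlier samples, anatomical-site or
demographic covariates, and read-level artifacts. Passing tests on
this generator therefore demonstrate the statistical machinery is
correct under the stated model — not that real multi-study skin
biopsies satisfy that model. The directional-consistency observation,
for instance, is expected almost surely under this generator (shared
DEGs are planted with a common direction) and is informative only on
real data.

`generate_enrichment_scores()` draws scores as Normal(group mean,
`score_sd` = 0.05) truncated at zero with baselines uniform on
[0.1, 0.6]; a planted shift is expressed in SD units so the planted
standardized effect equals the shift. Truncation is negligible at
these baselines but keeps the scores in the valid range.

## Numerical and reproducibility notes

* All simulation and subsampling functions take integer seeds, set
  the RNG locally and restore the caller's RNG state; identical seed
  and configuration give byte-identical outputs.
* The lasso solver converges on a max-coefficient-change tolerance of
  1e-8 with an objective-decrease guard; IRLS weights are floored at
  1e-5 to keep working responses finite on separable data.
* Validation problem sizes were chosen to exercise each property at
  meaningful scale while keeping the default suite quick: 600-sample
  cohorts for classifier twins, 2000 genes x 80 samples for
  interaction recovery, 5000 genes for variance-prior recovery, and
  200 score replicates for null error control.
* Degenerate inputs have defined behavior rather than NaNs: all-tied
  Kruskal–Wallis returns H = 0; zero pooled variance makes Cohen's D
  an explicit error; a single batch level makes batch removal the
  identity; probability exactly at the threshold is called male.

## Known limitations

* The fixed-effect study blocking assumes study affects all samples
  of a study equally per gene; it cannot absorb study-by-group
  interactions, which are confounded with the biology when a study
  contributes only one group.
* The classifier is only as good as the marker annotation; samples
  from individuals with atypical sex-chromosome expression (e.g. XIST
  silencing in some tumors) can be misclassified, which is why
  reported labels are never overwritten.
* The composition z-test compares two *estimated* effect sizes and is
  underpowered for modest sex differences at typical cohort sizes, as
  quantified above.
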