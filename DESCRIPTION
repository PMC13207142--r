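Package: sexstrat
Title: Sex-Stratified Differential Expression and Cell-Composition
    Analysis for Multi-Study RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for sex-stratified meta-analysis of
    bulk RNA-seq count data across multiple studies. Provides
    expression-based inference of biological sex from six
    sex-chromosome marker genes (XIST and five Y-linked genes) using
    L1-penalized logistic regression with cross-validated penalty
    selection; library-size and low-expression quality filters; TMM
    normalization, logCPM/RPKM transforms and voom-style precision
    weights; study-blocked weighted linear modeling with
    empirical-Bayes moderation, sex-specific and sex-by-disease
    interaction contrasts, Benjamini-Hochberg DEG calling and Venn
    partitioning with direction labels; batch-corrected classical MDS;
    and sex-stratified cell-type composition statistics
    (Kruskal-Wallis with Dunn's post hoc, per-sex Cohen's D and a
    z-test on the male-female difference in effect sizes with FDR
    control). A negative-binomial multi-study simulator with planted
    effects makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    edgeR,
    limma,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    glmnet,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
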