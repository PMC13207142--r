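# Independent oracle implementations used to cross-check the package.
# These are deliberately written from the textbook definitions, not by
# calling the code paths they verify.

# Brute-force TMM: doubly trimmed, inverse-variance-weighted mean of
# gene-wise log-ratios against the upper-quartile reference sample.
oracle_tmm <- function(counts, logratio_trim = 0.3, sum_trim = 0.05) {
  lib <- colSums(counts)
  f75 <- vapply(seq_len(ncol(counts)), function(j) {
    stats::quantile(counts[, j] / lib[j], probs = 0.75, names = FALSE)
  }, numeric(1))
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    obs <- counts[, j]; rfc <- counts[, ref]
    nO <- lib[j]; nR <- lib[ref]
    logR <- log2((obs / nO) / (rfc / nR))
    absE <- (log2(obs / nO) + log2(rfc / nR)) / 2
    v <- (nO - obs) / (nO * obs) + (nR - rfc) / (nR * rfc)
    fin <- is.finite(logR) & is.finite(absE)
    logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
    if (max(abs(logR)) < 1e-6) return(1)
    n <- length(logR)
    loL <- floor(n * logratio_trim) + 1; hiL <- n + 1 - loL
    loS <- floor(n * sum_trim) + 1; hiS <- n + 1 - loS
    keep <- rank(logR) >= loL & rank(logR) <= hiL &
      rank(absE) >= loS & rank(absE) <= hiS
    2^(sum(logR[keep] / v[keep]) / sum(1 / v[keep]))
  }, numeric(1))
  f / exp(mean(log(f)))
}

# Step-up FDR from the definition: adj p for the k-th smallest p is
# min over j >= k of n * p_(j) / j, capped at 1.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  for (k in seq_len(n)) {
    adj[o[k]] <- min(1, min(n * p[o][k:n] / (k:n)))
  }
  adj
}

# Normal-approximation rank-sum z for two groups, with tie correction,
# written from the Wilcoxon/Dunn two-group formulas.
oracle_ranksum_z <- function(x, g) {
  g <- factor(g)
  stopifnot(nlevels(g) == 2L)
  N <- length(x)
  r <- rank(x)
  n1 <- sum(g == levels(g)[1]); n2 <- N - n1
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  (mean(r[g == levels(g)[1]]) - mean(r[g == levels(g)[2]])) /
    sqrt((N * (N + 1) / 12 - tie_term) * (1 / n1 + 1 / n2))
}

# Mean silhouette width on a single coordinate for a 2-level grouping.
silhouette1d <- function(v, g) {
  g <- as.character(g)
  s <- vapply(seq_along(v), function(i) {
    same <- g == g[i]; same[i] <- FALSE
    a <- mean(abs(v[i] - v[same]))
    b <- mean(abs(v[i] - v[!same]))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}
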