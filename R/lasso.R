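# L1-penalized logistic regression by coordinate descent over an IRLS
# quadratic approximation (the standard GLM lasso scheme). The
# objective minimized is
#
#   -(1/n) * loglik(b0, beta) + lambda * sum(|beta|)
#
# with the intercept unpenalized. Features are standardized internally
# (mean 0, variance 1 with the 1/n variance convention) so the penalty
# is comparable across genes; coefficients are returned on the
# original scale. The per-lambda solver lives in src/lasso_cd.cpp; at
# lambda = 0 it reduces to plain IRLS and matches an unpenalized
# logistic fit.

# Fit the whole regularization path (decreasing lambda, warm starts).
# Returns intercepts and coefficients on the ORIGINAL feature scale.
lasso_logistic_path <- function(X, y, lambdas, tol = 1e-8) {
  ctr <- colMeans(X)
  scl <- sqrt(colMeans(sweep(X, 2, ctr)^2))
  scl[scl == 0] <- 1  # constant feature: leave unscaled, penalty kills it
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")

  ord <- order(lambdas, decreasing = TRUE)
  fit <- .lasso_cd_path(Xs, y, lambdas[ord], b0_init = stats::qlogis(mean(y)),
                        tol = tol)
  B <- matrix(0, nrow = ncol(X), ncol = length(lambdas),
              dimnames = list(colnames(X), NULL))
  B0 <- numeric(length(lambdas))
  beta_orig <- fit$coefficients / scl
  B[, ord] <- beta_orig
  B0[ord] <- fit$intercepts - drop(crossprod(beta_orig, ctr))
  list(intercepts = B0, coefficients = B)
}

# Smallest lambda at which all penalized coefficients are zero.
lasso_lambda_max <- function(X, y) {
  ctr <- colMeans(X)
  scl <- sqrt(colMeans(sweep(X, 2, ctr)^2))
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  max(abs(crossprod(Xs, y - mean(y)))) / nrow(X)
}

binomial_deviance <- function(y, p) {
  p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
  -2 * mean(y * log(p) + (1 - y) * log(1 - p))
}

# Class-stratified fold assignment, deterministic given the seed.
stratified_folds <- function(y, n_folds, seed) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (cls in unique(y)) {
      idx <- which(y == cls)
      fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
    fold
  })
}
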