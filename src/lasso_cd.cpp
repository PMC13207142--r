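#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Coordinate descent over an IRLS quadratic approximation for
// L1-penalized logistic regression. Objective:
//   -(1/n) loglik(b0, beta) + lambda * sum(|beta|),
// intercept unpenalized. X is expected standardized by the caller.

// Penalized objective -(1/n) loglik + lambda * ||beta||_1
static double objective(const NumericMatrix& X, const NumericVector& y,
                        double lambda, double b0, const std::vector<double>& beta) {
  const int n = X.nrow(), p = X.ncol();
  double nll = 0.0, pen = 0.0;
  for (int i = 0; i < n; ++i) {
    double e = b0;
    for (int j = 0; j < p; ++j) e += X(i, j) * beta[j];
    // log(1 + exp(e)) - y*e, computed stably
    nll += (e > 0 ? e + std::log1p(std::exp(-e)) : std::log1p(std::exp(e))) - y[i] * e;
  }
  for (int j = 0; j < p; ++j) pen += std::fabs(beta[j]);
  return nll / n + lambda * pen;
}

static void fit_one_lambda(const NumericMatrix& X, const NumericVector& y,
                           double lambda, double& b0, std::vector<double>& beta,
                           double tol, int max_outer, int max_inner) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> eta(n), w(n), r(n);
  std::vector<double> beta_prev(p);
  double obj_prev = objective(X, y, lambda, b0, beta);

  for (int outer = 0; outer < max_outer; ++outer) {
    double b0_prev = b0;
    for (int j = 0; j < p; ++j) beta_prev[j] = beta[j];

    // IRLS working weights and residuals at the current estimate
    for (int i = 0; i < n; ++i) {
      double e = b0;
      for (int j = 0; j < p; ++j) e += X(i, j) * beta[j];
      eta[i] = e;
      double mu = 1.0 / (1.0 + std::exp(-e));
      double wi = mu * (1.0 - mu);
      if (wi < 1e-5) wi = 1e-5;
      w[i] = wi;
      r[i] = (y[i] - mu) / wi;  // z - eta
    }

    for (int inner = 0; inner < max_inner; ++inner) {
      double max_delta = 0.0;
      for (int j = 0; j < p; ++j) {
        double num = 0.0, den = 0.0;
        for (int i = 0; i < n; ++i) {
          const double xij = X(i, j);
          num += w[i] * xij * r[i];
          den += w[i] * xij * xij;
        }
        den /= n;
        num = num / n + den * beta[j];
        double bj = 0.0;
        const double excess = std::fabs(num) - lambda;
        if (excess > 0.0 && den > 0.0) bj = (num > 0.0 ? excess : -excess) / den;
        const double diff = bj - beta[j];
        if (diff != 0.0) {
          for (int i = 0; i < n; ++i) r[i] -= X(i, j) * diff;
          beta[j] = bj;
          const double ad = std::fabs(diff);
          if (ad > max_delta) max_delta = ad;
        }
      }
      double sw = 0.0, swr = 0.0;
      for (int i = 0; i < n; ++i) { sw += w[i]; swr += w[i] * r[i]; }
      const double d0 = swr / sw;
      if (d0 != 0.0) {
        b0 += d0;
        for (int i = 0; i < n; ++i) r[i] -= d0;
        const double ad = std::fabs(d0);
        if (ad > max_delta) max_delta = ad;
      }
      if (max_delta < tol) break;
    }

    double max_change = std::fabs(b0 - b0_prev);
    for (int j = 0; j < p; ++j) {
      const double c = std::fabs(beta[j] - beta_prev[j]);
      if (c > max_change) max_change = c;
    }
    if (max_change < tol * 10.0) break;
    const double obj = objective(X, y, lambda, b0, beta);
    if (obj_prev - obj < 1e-10 * (std::fabs(obj_prev) + 1e-10)) break;
    obj_prev = obj;
  }
}

// [[Rcpp::export(name = ".lasso_cd_path")]]
List lasso_cd_path(NumericMatrix X, NumericVector y, NumericVector lambdas,
                   double b0_init, double tol = 1e-8,
                   int max_outer = 100, int max_inner = 200) {
  const int p = X.ncol(), L = lambdas.size();
  NumericVector intercepts(L);
  NumericMatrix coefs(p, L);
  double b0 = b0_init;
  std::vector<double> beta(p, 0.0);
  // caller passes lambdas in decreasing order; warm-start along the path
  for (int k = 0; k < L; ++k) {
    fit_one_lambda(X, y, lambdas[k], b0, beta, tol, max_outer, max_inner);
    intercepts[k] = b0;
    for (int j = 0; j < p; ++j) coefs(j, k) = beta[j];
  }
  return List::create(_["intercepts"] = intercepts, _["coefficients"] = coefs);
}
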