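// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// In-place Cholesky solve for small SPD systems (avoids LAPACK call
// overhead at the design dimensions used here).  A must hold the lower
// triangle; returns false if a pivot collapses.
static bool chol_solve_small(mat& A, vec& b) {
  const uword k = A.n_rows;
  for (uword j = 0; j < k; ++j) {
    double d = A(j, j);
    for (uword p = 0; p < j; ++p) d -= A(j, p) * A(j, p);
    if (d <= 0.0) return false;
    d = std::sqrt(d);
    A(j, j) = d;
    for (uword i = j + 1; i < k; ++i) {
      double s = A(i, j);
      for (uword p = 0; p < j; ++p) s -= A(i, p) * A(j, p);
      A(i, j) = s / d;
    }
  }
  for (uword i = 0; i < k; ++i) {          // forward solve L z = b
    double s = b[i];
    for (uword p = 0; p < i; ++p) s -= A(i, p) * b[p];
    b[i] = s / A(i, i);
  }
  for (uword ii = k; ii > 0; --ii) {       // back solve L' x = z
    uword i = ii - 1;
    double s = b[i];
    for (uword p = i + 1; p < k; ++p) s -= A(p, i) * b[p];
    b[i] = s / A(i, i);
  }
  return true;
}

// Quantile regression by epsilon-smoothed iteratively reweighted least
// squares: residual r gets weight {tau or (1-tau)} / max(|r|, eps);
// iterate weighted LS until the check loss stabilises.  One fused pass
// per iteration accumulates the normal equations and the loss.
// [[Rcpp::export(name = ".irls_qr")]]
Rcpp::List irls_qr(const arma::mat& X, const arma::vec& y, double tau,
                   int maxit = 100, double tol = 1e-8, double eps = 1e-6) {
  const uword n = X.n_rows, k = X.n_cols;
  const mat Xt = X.t();  // contiguous per-observation rows
  const double* yp = y.memptr();
  mat A(k, k);
  vec rhs(k), beta(k, fill::zeros);

  // initial unweighted least squares
  A.zeros();
  rhs.zeros();
  for (uword j = 0; j < k; ++j) A(j, j) = 1e-10;
  for (uword i = 0; i < n; ++i) {
    const double* xi = Xt.colptr(i);
    for (uword c1 = 0; c1 < k; ++c1) {
      double x1 = xi[c1];
      rhs[c1] += x1 * yp[i];
      for (uword c2 = c1; c2 < k; ++c2) A(c2, c1) += x1 * xi[c2];
    }
  }
  if (chol_solve_small(A, rhs)) beta = rhs;

  double lossOld = datum::inf, loss = 0;
  bool converged = false;
  int it = 0;
  for (it = 0; it < maxit; ++it) {
    A.zeros();
    rhs.zeros();
    loss = 0;
    for (uword j = 0; j < k; ++j) A(j, j) = 1e-10;
    for (uword i = 0; i < n; ++i) {
      const double* xi = Xt.colptr(i);
      double pred = 0;
      for (uword c = 0; c < k; ++c) pred += xi[c] * beta[c];
      double ri = yp[i] - pred;
      loss += ri * (tau - (ri < 0 ? 1.0 : 0.0));
      double a = (ri >= 0) ? tau : 1.0 - tau;
      double d = std::abs(ri);
      if (d < eps) d = eps;
      double w = a / d;
      for (uword c1 = 0; c1 < k; ++c1) {
        double wx = w * xi[c1];
        rhs[c1] += wx * yp[i];
        for (uword c2 = c1; c2 < k; ++c2)
          A(c2, c1) += wx * xi[c2];
      }
    }
    loss /= n;  // loss of the current beta
    if (std::abs(lossOld - loss) < tol * (std::abs(lossOld) + 1e-12)) {
      converged = true;
      break;
    }
    lossOld = loss;
    if (!chol_solve_small(A, rhs)) break;
    beta = rhs;
  }

  double finalLoss = 0;                     // loss at the returned beta
  for (uword i = 0; i < n; ++i) {
    const double* xi = Xt.colptr(i);
    double pred = 0;
    for (uword c = 0; c < k; ++c) pred += xi[c] * beta[c];
    double ri = yp[i] - pred;
    finalLoss += ri * (tau - (ri < 0 ? 1.0 : 0.0));
  }
  return Rcpp::List::create(Rcpp::Named("coef") = beta,
                            Rcpp::Named("loss") = finalLoss / n,
                            Rcpp::Named("iterations") = it + 1,
                            Rcpp::Named("converged") = converged);
}

// Logistic regression by Newton-Raphson with step halving.  X must
// already contain the intercept column.  Coefficients with |b| > cap
// are capped (separation guard) and the log-likelihood re-evaluated at
// the capped value.
// [[Rcpp::export(name = ".newton_logistic")]]
Rcpp::List newton_logistic(const arma::mat& X, const arma::vec& d,
                           double cap = 15.0, int maxit = 50,
                           double tol = 1e-10) {
  const uword n = X.n_rows, k = X.n_cols;
  vec beta(k, fill::zeros);
  auto loglik = [&](const vec& b) {
    vec eta = X * b;
    double ll = 0;
    for (uword i = 0; i < n; ++i)
      ll += d[i] * eta[i] - std::log1p(std::exp(eta[i]));
    return ll;
  };
  double ll = loglik(beta);
  bool converged = false;
  for (int it = 0; it < maxit; ++it) {
    vec eta = X * beta;
    vec mu = 1.0 / (1.0 + exp(-eta));
    vec wv = mu % (1.0 - mu);
    mat A(k, k, fill::zeros);
    vec g(k, fill::zeros);
    for (uword j = 0; j < k; ++j) A(j, j) = 1e-10;
    const double* xp = X.memptr();
    for (uword i = 0; i < n; ++i) {
      double resid = d[i] - mu[i];
      double w = wv[i];
      for (uword c1 = 0; c1 < k; ++c1) {
        double x1 = xp[c1 * n + i];
        g[c1] += x1 * resid;
        for (uword c2 = c1; c2 < k; ++c2)
          A(c2, c1) += w * x1 * xp[c2 * n + i];
      }
    }
    vec step = g;
    if (!chol_solve_small(A, step)) break;
    double llNew = loglik(beta + step);
    int halvings = 0;
    while (llNew < ll && halvings < 20) {
      step *= 0.5;
      llNew = loglik(beta + step);
      ++halvings;
    }
    beta += step;
    if (std::abs(llNew - ll) < tol * (std::abs(ll) + 1e-12)) {
      ll = llNew;
      converged = true;
      break;
    }
    ll = llNew;
  }
  bool separated = false;
  for (uword j = 0; j < k; ++j)
    if (std::abs(beta[j]) > cap) {
      separated = true;
      beta[j] = beta[j] > 0 ? cap : -cap;
    }
  if (separated) ll = loglik(beta);
  return Rcpp::List::create(Rcpp::Named("coef") = beta,
                            Rcpp::Named("logLik") = ll,
                            Rcpp::Named("converged") = converged,
                            Rcpp::Named("separated") = separated);
}
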