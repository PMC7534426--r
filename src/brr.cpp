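// Single-site Gibbs sampler for Bayesian ridge regression:
//   y_i = mu + sum_j X_ij a_j + e_i,  a_j ~ N(0, varB),  e_i ~ N(0, varE),
// with scaled-inverse-chi-square priors on varB and varE. Residuals are
// updated in place after every marker move (O(n) per marker).
//
// X is expected column-centred. Negative fixVarE/fixVarB leave the variance
// components free; non-negative values clamp them (used for closed-form
// ridge cross-checks).

#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// [[Rcpp::export]]
List cpp_brr_gibbs(NumericMatrix X, NumericVector y, int nIter, int burnIn,
                   double dfPrior, double Se, double Sm, double fixVarE,
                   double fixVarB) {
  const int n = X.nrow();
  const int p = X.ncol();
  if (y.size() != n) stop("length(y) != nrow(X)");
  if (burnIn >= nIter) stop("burnIn must be smaller than nIter");
  RNGScope scope;

  std::vector<double> xtx(p);
  for (int j = 0; j < p; ++j) {
    const double* xj = &X(0, j);
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += xj[i] * xj[i];
    xtx[j] = s;
  }

  double mu = mean(y);
  std::vector<double> b(p, 0.0), e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;

  double varE = (fixVarE >= 0) ? fixVarE : Se / (dfPrior + 2.0);
  double varB = (fixVarB >= 0) ? fixVarB : Sm / (dfPrior + 2.0);
  if (varE <= 0) varE = 1e-8;
  if (varB <= 0) varB = 1e-8;

  double muSum = 0.0, varESum = 0.0, varBSum = 0.0;
  std::vector<double> bSum(p, 0.0);
  int nKept = 0;

  for (int it = 0; it < nIter; ++it) {
    // intercept
    double se = 0.0;
    for (int i = 0; i < n; ++i) se += e[i];
    const double muNew = (se / n + mu) + norm_rand() * std::sqrt(varE / n);
    const double dMu = mu - muNew;
    for (int i = 0; i < n; ++i) e[i] += dMu;
    mu = muNew;

    // marker effects
    const double lambda = varE / varB;
    for (int j = 0; j < p; ++j) {
      if (xtx[j] <= 0) { b[j] = 0.0; continue; }
      const double* xj = &X(0, j);
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) rhs += xj[i] * e[i];
      rhs += xtx[j] * b[j];
      const double c = xtx[j] + lambda;
      const double bNew = rhs / c + norm_rand() * std::sqrt(varE / c);
      const double d = b[j] - bNew;
      if (d != 0.0)
        for (int i = 0; i < n; ++i) e[i] += xj[i] * d;
      b[j] = bNew;
    }

    // variance components
    if (fixVarB < 0) {
      double ssb = 0.0;
      for (int j = 0; j < p; ++j) ssb += b[j] * b[j];
      varB = (ssb + Sm) / R::rchisq(dfPrior + p);
    }
    if (fixVarE < 0) {
      double sse = 0.0;
      for (int i = 0; i < n; ++i) sse += e[i] * e[i];
      varE = (sse + Se) / R::rchisq(dfPrior + n);
    }

    if (it >= burnIn) {
      ++nKept;
      muSum += mu;
      varESum += varE;
      varBSum += varB;
      for (int j = 0; j < p; ++j) bSum[j] += b[j];
    }
  }

  NumericVector bHat(p);
  for (int j = 0; j < p; ++j) bHat[j] = bSum[j] / nKept;
  return List::create(_["mu"] = muSum / nKept, _["effects"] = bHat,
                      _["varE"] = varESum / nKept, _["varB"] = varBSum / nKept,
                      _["nKept"] = nKept);
}
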