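#include <Rcpp.h>
using namespace Rcpp;

// Margin-based elimination criterion for kernel RFE with an RBF kernel.
//
// For feature i, the criterion is the change in the SVM dual objective when
// the feature is removed from the kernel at fixed dual variables:
//   J_i = (1/2) a'Ka - (1/2) a'K^{(-i)}a
// with K the RBF kernel on the support vectors and K^{(-i)} the kernel
// recomputed without column i. Since K = exp(-g * sum_j d_j) with
// d_j[s,t] = (x[s,j]-x[t,j])^2, removing feature i multiplies K elementwise
// by exp(g * d_i). With W[s,t] = a_s a_t K[s,t] this gives
//   J_i = (1/2) sum(W) - (1/2) sum(W .* exp(g * d_i)).
// W is symmetric, so only the upper triangle is visited.
//
// [[Rcpp::export]]
NumericVector rfe_rbf_criteria(NumericMatrix X, NumericMatrix W,
                               double gamma) {
  const int m = X.nrow();
  const int d = X.ncol();
  NumericVector crit(d);

  double sumW = 0.0;
  for (int s = 0; s < m; ++s) {
    sumW += W(s, s);
    for (int t = s + 1; t < m; ++t) sumW += 2.0 * W(s, t);
  }

  for (int i = 0; i < d; ++i) {
    const double *xi = &X(0, i);
    double acc = 0.0;
    for (int s = 0; s < m; ++s) {
      acc += W(s, s);  // diagonal: d_i = 0
      const double xs = xi[s];
      for (int t = s + 1; t < m; ++t) {
        const double diff = xs - xi[t];
        acc += 2.0 * W(s, t) * std::exp(gamma * diff * diff);
      }
    }
    crit[i] = 0.5 * (sumW - acc);
  }
  return crit;
}
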