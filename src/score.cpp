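// Batch residual-sum-of-squares for many small regressions sharing one
// Gram matrix.  G is crossprod(cbind(design columns, y)); each candidate
// model is a set of design-column indices (1-based into G), and its RSS is
// yty - g' (G_SS)^{-1} g with g = G[S, ycol], solved by a dense Cholesky.
// Singular (rank-deficient) models yield NA.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector rss_from_gram(NumericMatrix G, List sets, int ycol) {
  const int ns = sets.size();
  const double yty = G(ycol - 1, ycol - 1);
  NumericVector out(ns);
  std::vector<double> a, g;
  for (int s = 0; s < ns; ++s) {
    IntegerVector idx = sets[s];
    const int k = idx.size();
    if (k == 0) { out[s] = yty; continue; }
    a.assign((size_t)k * k, 0.0);
    g.resize(k);
    for (int i = 0; i < k; ++i) {
      g[i] = G(idx[i] - 1, ycol - 1);
      for (int j = 0; j <= i; ++j)
        a[i * k + j] = G(idx[i] - 1, idx[j] - 1);
    }
    // Cholesky (lower), fail -> NA
    bool ok = true;
    for (int i = 0; i < k && ok; ++i) {
      for (int j = 0; j <= i; ++j) {
        double sum = a[i * k + j];
        for (int t = 0; t < j; ++t) sum -= a[i * k + t] * a[j * k + t];
        if (i == j) {
          // relative tolerance against the diagonal scale
          if (sum <= 1e-10 * std::max(1.0, G(idx[i] - 1, idx[i] - 1))) {
            ok = false;
            break;
          }
          a[i * k + i] = std::sqrt(sum);
        } else {
          a[i * k + j] = sum / a[j * k + j];
        }
      }
    }
    if (!ok) { out[s] = NA_REAL; continue; }
    // solve L z = g, then L' b = z; rss = yty - z'z (since b'Ab = z'z)
    double zz = 0.0;
    std::vector<double> z(k);
    for (int i = 0; i < k; ++i) {
      double sum = g[i];
      for (int t = 0; t < i; ++t) sum -= a[i * k + t] * z[t];
      z[i] = sum / a[i * k + i];
      zz += z[i] * z[i];
    }
    double rss = yty - zz;
    out[s] = rss > 0 ? rss : 0.0;
  }
  return out;
}
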