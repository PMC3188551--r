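// Inner loops of the SOM hierarchy.
//
// Both kernels stream the (neurons x connections) weight/index matrices in
// column-major order with one random gather into the presynaptic firing
// vector; this is the hot path of training (hundreds of thousands of
// presentations) and is memory-latency bound in interpreted form.

#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// h_i = sum_j w_ij * y[idx_ij]   (idx is 1-based)
// [[Rcpp::export(name = ".cpp_activations")]]
NumericVector cpp_activations(const IntegerMatrix& idx,
                              const NumericMatrix& w,
                              const NumericVector& y) {
  const int n = idx.nrow(), m = idx.ncol(), ny = y.size();
  NumericVector h(n);
  for (int j = 0; j < m; ++j) {
    const int* ic = &idx(0, j);
    const double* wc = &w(0, j);
    for (int i = 0; i < n; ++i) {
      const int k = ic[i] - 1;
      if (k < 0 || k >= ny) stop("afferent index out of bounds");
      h[i] += wc[i] * y[k];
    }
  }
  return h;
}

// w_ij += rate * y_post_i * y_pre[idx_ij], then unit-normalise each row.
// Returns a new matrix; the input is untouched.
// [[Rcpp::export(name = ".cpp_hebbian")]]
NumericMatrix cpp_hebbian(const IntegerMatrix& idx,
                          const NumericMatrix& w,
                          const NumericVector& y_pre,
                          const NumericVector& y_post,
                          double rate) {
  const int n = idx.nrow(), m = idx.ncol(), ny = y_pre.size();
  NumericMatrix out(n, m);
  std::vector<double> ss(n, 0.0);
  for (int j = 0; j < m; ++j) {
    const int* ic = &idx(0, j);
    const double* wc = &w(0, j);
    double* oc = &out(0, j);
    for (int i = 0; i < n; ++i) {
      const int k = ic[i] - 1;
      if (k < 0 || k >= ny) stop("afferent index out of bounds");
      const double v = wc[i] + rate * y_post[i] * y_pre[k];
      oc[i] = v;
      ss[i] += v * v;
    }
  }
  for (int i = 0; i < n; ++i) ss[i] = ss[i] > 0 ? 1.0 / std::sqrt(ss[i]) : 1.0;
  for (int j = 0; j < m; ++j) {
    double* oc = &out(0, j);
    for (int i = 0; i < n; ++i) oc[i] *= ss[i];
  }
  return out;
}
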