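#include <Rcpp.h>
using namespace Rcpp;

// VAR(p) recursion: x_t = sum_k A_k x_{t-k} + e_t.
// coeffs is M x (M*p), the horizontal stack [A_1 | A_2 | ... | A_p].
// innov is M x (burnin + n) of pre-drawn innovations (already correlated).
// Returns M x n; the first `burnin` steps are generated and discarded so the
// process forgets its zero initial state.
// [[Rcpp::export]]
NumericMatrix var_recursion(NumericMatrix coeffs, NumericMatrix innov,
                            int p, int burnin) {
  const int M = innov.nrow();
  const int total = innov.ncol();
  const int n = total - burnin;
  if (n <= 0) stop("innovations shorter than burn-in");
  std::vector<double> buf((size_t)M * total, 0.0); // column-major M x total
  for (int t = 0; t < total; ++t) {
    double *xt = &buf[(size_t)M * t];
    for (int i = 0; i < M; ++i) xt[i] = innov(i, t);
    int kmax = std::min(p, t);
    for (int k = 1; k <= kmax; ++k) {
      const double *xlag = &buf[(size_t)M * (t - k)];
      const int off = (k - 1) * M;
      for (int i = 0; i < M; ++i) {
        double acc = 0.0;
        for (int j = 0; j < M; ++j) acc += coeffs(i, off + j) * xlag[j];
        xt[i] += acc;
      }
    }
  }
  NumericMatrix out(M, n);
  for (int t = 0; t < n; ++t)
    for (int i = 0; i < M; ++i) out(i, t) = buf[(size_t)M * (burnin + t) + i];
  return out;
}
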