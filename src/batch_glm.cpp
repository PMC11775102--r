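#include <Rcpp.h>
using namespace Rcpp;

// Solve, for each gene g, the p x p system M_g beta = b_g, where M is
// genes x p^2 (row-major per gene) and B is genes x p. Returns the
// solutions (genes x p) and the log-determinant of each M_g (used for the
// Cox-Reid adjusted profile likelihood). Plain Gaussian elimination with
// partial pivoting; p is small (design columns).
// [[Rcpp::export]]
List batch_solve_cpp(NumericMatrix M, NumericMatrix B) {
  const int G = M.nrow();
  const int p = B.ncol();
  NumericMatrix out(G, p);
  NumericVector logdet(G);
  std::vector<double> a(p * p), b(p);
  for (int g = 0; g < G; ++g) {
    for (int i = 0; i < p * p; ++i) a[i] = M(g, i);
    for (int i = 0; i < p; ++i) b[i] = B(g, i);
    double ld = 0.0;
    bool ok = true;
    for (int c = 0; c < p; ++c) {
      int piv = c;
      for (int r = c + 1; r < p; ++r)
        if (std::fabs(a[r * p + c]) > std::fabs(a[piv * p + c])) piv = r;
      if (piv != c) {
        for (int k = 0; k < p; ++k) std::swap(a[c * p + k], a[piv * p + k]);
        std::swap(b[c], b[piv]);
      }
      double d = a[c * p + c];
      if (std::fabs(d) < 1e-300) { ok = false; break; }
      ld += std::log(std::fabs(d));
      for (int r = c + 1; r < p; ++r) {
        double f = a[r * p + c] / d;
        for (int k = c; k < p; ++k) a[r * p + k] -= f * a[c * p + k];
        b[r] -= f * b[c];
      }
    }
    if (!ok) {
      for (int k = 0; k < p; ++k) out(g, k) = NA_REAL;
      logdet[g] = NA_REAL;
      continue;
    }
    for (int c = p - 1; c >= 0; --c) {
      double s = b[c];
      for (int k = c + 1; k < p; ++k) s -= a[c * p + k] * out(g, k);
      out(g, c) = s / a[c * p + c];
    }
    logdet[g] = ld;
  }
  return List::create(_["beta"] = out, _["logdet"] = logdet);
}
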