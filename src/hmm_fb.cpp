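#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward pass for one chromosome.
// logE: bins x states log emission likelihoods; trans: states x states
// row-stochastic; init: length-states initial distribution.
// Returns log-likelihood, per-bin posteriors (gamma), and expected
// transition counts (xi summed over bins).
// [[Rcpp::export]]
List hmm_forward_backward_cpp(NumericMatrix logE, NumericMatrix trans,
                              NumericVector init) {
  const int T = logE.nrow();
  const int K = logE.ncol();
  NumericMatrix E(T, K);       // scaled emissions exp(logE - rowmax)
  NumericVector rowmax(T);
  for (int t = 0; t < T; ++t) {
    double m = logE(t, 0);
    for (int k = 1; k < K; ++k) if (logE(t, k) > m) m = logE(t, k);
    rowmax[t] = m;
    for (int k = 0; k < K; ++k) E(t, k) = std::exp(logE(t, k) - m);
  }
  NumericMatrix alpha(T, K);
  NumericVector c(T);
  // forward
  double s = 0.0;
  for (int k = 0; k < K; ++k) {
    alpha(0, k) = init[k] * E(0, k);
    s += alpha(0, k);
  }
  c[0] = s;
  for (int k = 0; k < K; ++k) alpha(0, k) /= s;
  for (int t = 1; t < T; ++t) {
    s = 0.0;
    for (int k = 0; k < K; ++k) {
      double a = 0.0;
      for (int j = 0; j < K; ++j) a += alpha(t - 1, j) * trans(j, k);
      a *= E(t, k);
      alpha(t, k) = a;
      s += a;
    }
    c[t] = s;
    for (int k = 0; k < K; ++k) alpha(t, k) /= s;
  }
  // backward + gamma + xi
  NumericMatrix gamma(T, K);
  NumericMatrix xi(K, K);
  NumericVector beta(K), betanew(K);
  for (int k = 0; k < K; ++k) {
    beta[k] = 1.0;
    gamma(T - 1, k) = alpha(T - 1, k);
  }
  for (int t = T - 2; t >= 0; --t) {
    // xi uses beta at t+1
    for (int j = 0; j < K; ++j) {
      double eb = E(t + 1, j) * beta[j] / c[t + 1];
      for (int i = 0; i < K; ++i)
        xi(i, j) += alpha(t, i) * trans(i, j) * eb;
    }
    double g = 0.0;
    for (int k = 0; k < K; ++k) {
      double b = 0.0;
      for (int j = 0; j < K; ++j)
        b += trans(k, j) * E(t + 1, j) * beta[j];
      betanew[k] = b / c[t + 1];
      gamma(t, k) = alpha(t, k) * betanew[k];
      g += gamma(t, k);
    }
    for (int k = 0; k < K; ++k) {
      gamma(t, k) /= g;
      beta[k] = betanew[k];
    }
  }
  double ll = 0.0;
  for (int t = 0; t < T; ++t) ll += std::log(c[t]) + rowmax[t];
  return List::create(_["loglik"] = ll, _["gamma"] = gamma, _["xi"] = xi);
}

// Sample a state path from a Markov chain (1-based states), given
// uniform(0,1) draws (one per bin) so randomness stays under R's RNG.
// [[Rcpp::export]]
IntegerVector markov_path_cpp(NumericMatrix trans, NumericVector init,
                              NumericVector u) {
  const int T = u.size();
  const int K = init.size();
  IntegerVector path(T);
  double acc = 0.0;
  int st = K - 1;
  for (int k = 0; k < K; ++k) {
    acc += init[k];
    if (u[0] <= acc) { st = k; break; }
  }
  path[0] = st + 1;
  for (int t = 1; t < T; ++t) {
    acc = 0.0;
    int nxt = K - 1;
    for (int k = 0; k < K; ++k) {
      acc += trans(st, k);
      if (u[t] <= acc) { nxt = k; break; }
    }
    st = nxt;
    path[t] = st + 1;
  }
  return path;
}
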