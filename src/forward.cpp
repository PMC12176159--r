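#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward recursion for the weighted PHMM likelihood.
//
// logwb is the T x N matrix of per-step weighted log emission-label terms,
// logwb(t, i) = w_t * (log f_i(y_t) + log g_i(z_t)), with the convention that
// a zero weight yields exactly 0 (the step contributes only a transition
// factor).  Each step is shifted by its row maximum before exponentiation so
// the recursion cannot under- or overflow even at T = 20000.
//
// Returns the log-likelihood; -Inf if the support is exhausted (e.g. labels
// jointly impossible under the transition structure).
// [[Rcpp::export]]
double forward_loglik_cpp(NumericMatrix logwb, NumericVector delta,
                          NumericMatrix Gamma) {
  const int T = logwb.nrow(), N = logwb.ncol();
  std::vector<double> phi(N), tmp(N);
  double ll = 0.0;

  for (int t = 0; t < T; ++t) {
    double m = R_NegInf;
    for (int i = 0; i < N; ++i)
      if (logwb(t, i) > m) m = logwb(t, i);
    if (m == R_NegInf) return R_NegInf;

    double sum = 0.0;
    if (t == 0) {
      for (int i = 0; i < N; ++i) {
        tmp[i] = delta[i] * std::exp(logwb(t, i) - m);
        sum += tmp[i];
      }
    } else {
      for (int j = 0; j < N; ++j) {
        double acc = 0.0;
        for (int i = 0; i < N; ++i) acc += phi[i] * Gamma(i, j);
        tmp[j] = acc * std::exp(logwb(t, j) - m);
        sum += tmp[j];
      }
    }
    if (sum <= 0.0 || !std::isfinite(sum)) return R_NegInf;
    for (int i = 0; i < N; ++i) phi[i] = tmp[i] / sum;
    ll += m + std::log(sum);
  }
  return ll;
}
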