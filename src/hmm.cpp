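#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward for one observation sequence.
// logB: T x S matrix of per-position emission log-likelihoods,
// pi: initial state distribution, A: row-stochastic transition matrix.
// Returns the sequence log-likelihood, posterior state probabilities
// gamma (T x S), and the expected transition counts summed over t
// (xisum, S x S), as needed by the Baum-Welch M-step.
// [[Rcpp::export(name = ".fb_cpp")]]
List fb_cpp(NumericMatrix logB, NumericVector pi, NumericMatrix A) {
  const int T = logB.nrow(), S = logB.ncol();
  NumericMatrix b(T, S);        // shifted emission likelihoods
  NumericVector shift(T);
  for (int t = 0; t < T; ++t) {
    double mx = logB(t, 0);
    for (int s = 1; s < S; ++s) if (logB(t, s) > mx) mx = logB(t, s);
    shift[t] = mx;
    for (int s = 0; s < S; ++s) b(t, s) = std::exp(logB(t, s) - mx);
  }
  NumericMatrix alpha(T, S), beta(T, S);
  NumericVector c(T);           // per-position scaling constants
  double loglik = 0.0;
  // forward
  for (int s = 0; s < S; ++s) alpha(0, s) = pi[s] * b(0, s);
  c[0] = 0.0;
  for (int s = 0; s < S; ++s) c[0] += alpha(0, s);
  for (int s = 0; s < S; ++s) alpha(0, s) /= c[0];
  for (int t = 1; t < T; ++t) {
    double ct = 0.0;
    for (int j = 0; j < S; ++j) {
      double acc = 0.0;
      for (int i = 0; i < S; ++i) acc += alpha(t - 1, i) * A(i, j);
      alpha(t, j) = acc * b(t, j);
      ct += alpha(t, j);
    }
    c[t] = ct;
    for (int j = 0; j < S; ++j) alpha(t, j) /= ct;
  }
  for (int t = 0; t < T; ++t) loglik += std::log(c[t]) + shift[t];
  // backward
  for (int s = 0; s < S; ++s) beta(T - 1, s) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int i = 0; i < S; ++i) {
      double acc = 0.0;
      for (int j = 0; j < S; ++j)
        acc += A(i, j) * b(t + 1, j) * beta(t + 1, j);
      beta(t, i) = acc / c[t + 1];
    }
  }
  // posteriors and expected transition counts
  NumericMatrix gamma(T, S), xisum(S, S);
  for (int t = 0; t < T; ++t) {
    double rs = 0.0;
    for (int s = 0; s < S; ++s) { gamma(t, s) = alpha(t, s) * beta(t, s); rs += gamma(t, s); }
    for (int s = 0; s < S; ++s) gamma(t, s) /= rs;
  }
  for (int t = 0; t + 1 < T; ++t) {
    for (int i = 0; i < S; ++i) {
      const double ai = alpha(t, i);
      if (ai == 0.0) continue;
      for (int j = 0; j < S; ++j)
        xisum(i, j) += ai * A(i, j) * b(t + 1, j) * beta(t + 1, j) / c[t + 1];
    }
  }
  return List::create(_["loglik"] = loglik, _["gamma"] = gamma,
                      _["xisum"] = xisum);
}

// Viterbi decoding in log space; returns the 1-based MAP state path.
// [[Rcpp::export(name = ".viterbi_cpp")]]
IntegerVector viterbi_cpp(NumericMatrix logB, NumericVector logpi,
                          NumericMatrix logA) {
  const int T = logB.nrow(), S = logB.ncol();
  NumericMatrix delta(T, S);
  IntegerMatrix psi(T, S);
  for (int s = 0; s < S; ++s) delta(0, s) = logpi[s] + logB(0, s);
  for (int t = 1; t < T; ++t) {
    for (int j = 0; j < S; ++j) {
      double best = delta(t - 1, 0) + logA(0, j);
      int arg = 0;
      for (int i = 1; i < S; ++i) {
        const double v = delta(t - 1, i) + logA(i, j);
        if (v > best) { best = v; arg = i; }
      }
      delta(t, j) = best + logB(t, j);
      psi(t, j) = arg;
    }
  }
  IntegerVector path(T);
  int arg = 0;
  for (int s = 1; s < S; ++s) if (delta(T - 1, s) > delta(T - 1, arg)) arg = s;
  path[T - 1] = arg + 1;
  for (int t = T - 2; t >= 0; --t) {
    arg = psi(t + 1, arg);
    path[t] = arg + 1;
  }
  return path;
}
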