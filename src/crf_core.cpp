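// Linear-chain CRF inner loops: forward-backward statistics (log partition
// function, per-position tag marginals, expected transition counts) and
// Viterbi decoding. Forward-backward uses the scaled (normalized
// linear-space) recursion: emissions are shifted by their row maximum and
// transitions by their global maximum before exponentiation, and per-step
// normalization constants carry the magnitudes, so no intermediate ever
// overflows. Ties in Viterbi are broken toward the lowest tag index.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// E: n x K emission scores; T: K x K transition scores (from row to col)
// [[Rcpp::export]]
List crf_forward_stats(NumericMatrix E, NumericMatrix T) {
  int n = E.nrow(), K = E.ncol();

  double mT = T(0, 0);
  for (int j = 0; j < K; ++j)
    for (int k = 0; k < K; ++k)
      if (T(j, k) > mT) mT = T(j, k);
  std::vector<double> A(K * K);  // column-major: A[j + K*k] = exp(T(j,k)-mT)
  for (int k = 0; k < K; ++k)
    for (int j = 0; j < K; ++j)
      A[j + K * k] = std::exp(T(j, k) - mT);

  // e(i,k) = exp(E(i,k) - mE[i])
  std::vector<double> e(n * K), mE(n);
  for (int i = 0; i < n; ++i) {
    double m = E(i, 0);
    for (int k = 1; k < K; ++k) if (E(i, k) > m) m = E(i, k);
    mE[i] = m;
    for (int k = 0; k < K; ++k) e[i + n * k] = std::exp(E(i, k) - m);
  }

  NumericMatrix alpha(n, K), beta(n, K), marg(n, K), texp(K, K);
  std::vector<double> c(n);

  double s = 0.0;
  for (int k = 0; k < K; ++k) { alpha(0, k) = e[0 + n * k]; s += alpha(0, k); }
  c[0] = s;
  for (int k = 0; k < K; ++k) alpha(0, k) /= s;
  for (int i = 1; i < n; ++i) {
    s = 0.0;
    for (int k = 0; k < K; ++k) {
      double acc = 0.0;
      const double* Ak = &A[K * k];
      for (int j = 0; j < K; ++j) acc += alpha(i - 1, j) * Ak[j];
      double v = acc * e[i + n * k];
      alpha(i, k) = v;
      s += v;
    }
    c[i] = s;
    for (int k = 0; k < K; ++k) alpha(i, k) /= s;
  }

  double logZ = (n - 1) * mT;
  for (int i = 0; i < n; ++i) logZ += std::log(c[i]) + mE[i];

  for (int k = 0; k < K; ++k) beta(n - 1, k) = 1.0;
  std::vector<double> tmp(K);
  for (int i = n - 2; i >= 0; --i) {
    for (int k = 0; k < K; ++k)
      tmp[k] = e[(i + 1) + n * k] * beta(i + 1, k) / c[i + 1];
    for (int j = 0; j < K; ++j) {
      double acc = 0.0;
      for (int k = 0; k < K; ++k) acc += A[j + K * k] * tmp[k];
      beta(i, j) = acc;
    }
    // accumulate expected transition counts for step i -> i+1
    for (int k = 0; k < K; ++k) {
      double w = tmp[k];
      if (w == 0.0) continue;
      for (int j = 0; j < K; ++j)
        texp(j, k) += alpha(i, j) * A[j + K * k] * w;
    }
  }

  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k)
      marg(i, k) = alpha(i, k) * beta(i, k);

  return List::create(_["logZ"] = logZ, _["marginals"] = marg,
                      _["trans_expected"] = texp);
}

// [[Rcpp::export]]
IntegerVector crf_viterbi_path(NumericMatrix E, NumericMatrix T) {
  int n = E.nrow(), K = E.ncol();
  NumericMatrix delta(n, K);
  IntegerMatrix back(n, K);

  for (int k = 0; k < K; ++k) delta(0, k) = E(0, k);
  for (int i = 1; i < n; ++i)
    for (int k = 0; k < K; ++k) {
      int arg = 0;
      double best = delta(i - 1, 0) + T(0, k);
      for (int j = 1; j < K; ++j) {
        double s = delta(i - 1, j) + T(j, k);
        if (s > best) { best = s; arg = j; }  // strict > keeps lowest index
      }
      delta(i, k) = best + E(i, k);
      back(i, k) = arg;
    }

  IntegerVector path(n);
  int arg = 0;
  double best = delta(n - 1, 0);
  for (int k = 1; k < K; ++k)
    if (delta(n - 1, k) > best) { best = delta(n - 1, k); arg = k; }
  path[n - 1] = arg + 1;  // 1-based for R
  for (int i = n - 1; i > 0; --i) {
    arg = back(i, arg);
    path[i - 1] = arg + 1;
  }
  return path;
}
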