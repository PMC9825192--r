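#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward E-step for a discrete-state HMM whose per-bin
// observation log-likelihoods have been precomputed (logB, T x K). Multiple
// sequences (chromosomes) are concatenated; seq_starts gives the 0-based
// first index of each sequence, and the initial distribution is applied at
// every sequence start (transition reset at chromosome boundaries).
// [[Rcpp::export(name = ".hmm_estep")]]
List hmm_estep(NumericMatrix logB, NumericMatrix trans, NumericVector init,
               IntegerVector seq_starts) {
  const int T = logB.nrow(), K = logB.ncol(), S = seq_starts.size();
  NumericMatrix gamma(T, K);
  NumericMatrix xi(K, K);
  NumericVector init_counts(K);
  double loglik = 0.0;

  NumericMatrix B(T, K);
  for (int t = 0; t < T; ++t) {
    double m = logB(t, 0);
    for (int k = 1; k < K; ++k) if (logB(t, k) > m) m = logB(t, k);
    for (int k = 0; k < K; ++k) B(t, k) = std::exp(logB(t, k) - m);
    loglik += m;  // scaling constant folded into the log-likelihood
  }

  NumericMatrix alpha(T, K), beta(T, K);
  NumericVector c(T);

  for (int s = 0; s < S; ++s) {
    const int t0 = seq_starts[s];
    const int t1 = (s + 1 < S) ? seq_starts[s + 1] : T;
    // forward
    double norm = 0.0;
    for (int k = 0; k < K; ++k) {
      alpha(t0, k) = init[k] * B(t0, k);
      norm += alpha(t0, k);
    }
    c[t0] = norm;
    for (int k = 0; k < K; ++k) alpha(t0, k) /= norm;
    for (int t = t0 + 1; t < t1; ++t) {
      norm = 0.0;
      for (int k = 0; k < K; ++k) {
        double a = 0.0;
        for (int j = 0; j < K; ++j) a += alpha(t - 1, j) * trans(j, k);
        a *= B(t, k);
        alpha(t, k) = a;
        norm += a;
      }
      c[t] = norm;
      for (int k = 0; k < K; ++k) alpha(t, k) /= norm;
    }
    // backward
    for (int k = 0; k < K; ++k) beta(t1 - 1, k) = 1.0;
    for (int t = t1 - 2; t >= t0; --t) {
      for (int j = 0; j < K; ++j) {
        double b = 0.0;
        for (int k = 0; k < K; ++k)
          b += trans(j, k) * B(t + 1, k) * beta(t + 1, k);
        beta(t, j) = b / c[t + 1];
      }
    }
    // gamma, xi
    for (int t = t0; t < t1; ++t) {
      double g = 0.0;
      for (int k = 0; k < K; ++k) {
        gamma(t, k) = alpha(t, k) * beta(t, k);
        g += gamma(t, k);
      }
      for (int k = 0; k < K; ++k) gamma(t, k) /= g;
    }
    for (int k = 0; k < K; ++k) init_counts[k] += gamma(t0, k);
    for (int t = t0; t < t1 - 1; ++t) {
      for (int j = 0; j < K; ++j) {
        const double aj = alpha(t, j);
        for (int k = 0; k < K; ++k)
          xi(j, k) += aj * trans(j, k) * B(t + 1, k) * beta(t + 1, k) / c[t + 1];
      }
    }
    for (int t = t0; t < t1; ++t) loglik += std::log(c[t]);
  }

  return List::create(_["loglik"] = loglik, _["gamma"] = gamma,
                      _["xi"] = xi, _["init_counts"] = init_counts);
}

// Viterbi decoding in log space, with the same multi-sequence convention.
// Returns 1-based state indices.
// [[Rcpp::export(name = ".hmm_viterbi")]]
IntegerVector hmm_viterbi(NumericMatrix logB, NumericMatrix trans,
                          NumericVector init, IntegerVector seq_starts) {
  const int T = logB.nrow(), K = logB.ncol(), S = seq_starts.size();
  NumericMatrix ltr(K, K);
  NumericVector linit(K);
  for (int j = 0; j < K; ++j) {
    linit[j] = std::log(init[j]);
    for (int k = 0; k < K; ++k) ltr(j, k) = std::log(trans(j, k));
  }
  IntegerVector path(T);
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);
  for (int s = 0; s < S; ++s) {
    const int t0 = seq_starts[s];
    const int t1 = (s + 1 < S) ? seq_starts[s + 1] : T;
    for (int k = 0; k < K; ++k) delta(t0, k) = linit[k] + logB(t0, k);
    for (int t = t0 + 1; t < t1; ++t) {
      for (int k = 0; k < K; ++k) {
        double best = delta(t - 1, 0) + ltr(0, k);
        int arg = 0;
        for (int j = 1; j < K; ++j) {
          const double v = delta(t - 1, j) + ltr(j, k);
          if (v > best) { best = v; arg = j; }
        }
        delta(t, k) = best + logB(t, k);
        psi(t, k) = arg;
      }
    }
    int arg = 0;
    for (int k = 1; k < K; ++k) if (delta(t1 - 1, k) > delta(t1 - 1, arg)) arg = k;
    path[t1 - 1] = arg + 1;
    for (int t = t1 - 2; t >= t0; --t) {
      arg = psi(t + 1, arg);
      path[t] = arg + 1;
    }
  }
  return path;
}
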