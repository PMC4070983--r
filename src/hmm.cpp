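#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward over concatenated tracks.
// logB: T_total x K matrix of per-step emission log-densities.
// lens: steps per track (sum = T_total).
// Returns total loglik, per-step posteriors gamma (T_total x K),
// summed transition counts xi_sum (K x K), and summed first-step
// posteriors gamma1 (K).
// [[Rcpp::export]]
List hmm_forward_backward(NumericMatrix logB, IntegerVector lens,
                          NumericVector pi0, NumericMatrix trans) {
  const int K = logB.ncol();
  const int Ttot = logB.nrow();
  NumericMatrix gamma(Ttot, K);
  NumericMatrix xi(K, K);
  NumericVector gamma1(K);
  double loglik = 0.0;

  std::vector<double> alpha(Ttot * K), beta(Ttot * K), cvec(Ttot);
  int off = 0;
  for (int tr = 0; tr < lens.size(); ++tr) {
    const int T = lens[tr];
    // emission probs relative to per-step max for stability
    std::vector<double> bmax(T);
    for (int t = 0; t < T; ++t) {
      double m = logB(off + t, 0);
      for (int k = 1; k < K; ++k) m = std::max(m, logB(off + t, k));
      bmax[t] = m;
    }
    // forward with scaling
    double c0 = 0.0;
    for (int k = 0; k < K; ++k) {
      double a = pi0[k] * std::exp(logB(off, k) - bmax[0]);
      alpha[(off) * K + k] = a;
      c0 += a;
    }
    cvec[off] = c0;
    for (int k = 0; k < K; ++k) alpha[off * K + k] /= c0;
    loglik += std::log(c0) + bmax[0];
    for (int t = 1; t < T; ++t) {
      double ct = 0.0;
      for (int k = 0; k < K; ++k) {
        double s = 0.0;
        for (int j = 0; j < K; ++j) s += alpha[(off + t - 1) * K + j] * trans(j, k);
        double a = s * std::exp(logB(off + t, k) - bmax[t]);
        alpha[(off + t) * K + k] = a;
        ct += a;
      }
      cvec[off + t] = ct;
      for (int k = 0; k < K; ++k) alpha[(off + t) * K + k] /= ct;
      loglik += std::log(ct) + bmax[t];
    }
    // backward (scaled by same c)
    for (int k = 0; k < K; ++k) beta[(off + T - 1) * K + k] = 1.0;
    for (int t = T - 2; t >= 0; --t) {
      for (int k = 0; k < K; ++k) {
        double s = 0.0;
        for (int j = 0; j < K; ++j)
          s += trans(k, j) * std::exp(logB(off + t + 1, j) - bmax[t + 1]) *
               beta[(off + t + 1) * K + j];
        beta[(off + t) * K + k] = s / cvec[off + t + 1];
      }
    }
    // gamma and xi
    for (int t = 0; t < T; ++t) {
      double norm = 0.0;
      for (int k = 0; k < K; ++k) {
        double g = alpha[(off + t) * K + k] * beta[(off + t) * K + k];
        gamma(off + t, k) = g;
        norm += g;
      }
      for (int k = 0; k < K; ++k) gamma(off + t, k) /= norm;
    }
    for (int k = 0; k < K; ++k) gamma1[k] += gamma(off, k);
    for (int t = 0; t < T - 1; ++t) {
      for (int k = 0; k < K; ++k) {
        for (int j = 0; j < K; ++j) {
          xi(k, j) += alpha[(off + t) * K + k] * trans(k, j) *
                      std::exp(logB(off + t + 1, j) - bmax[t + 1]) *
                      beta[(off + t + 1) * K + j] / cvec[off + t + 1];
        }
      }
    }
    off += T;
  }
  return List::create(_["loglik"] = loglik, _["gamma"] = gamma,
                      _["xi_sum"] = xi, _["gamma1"] = gamma1);
}

// Viterbi most-likely state path per track; returns 1-based states.
// [[Rcpp::export]]
IntegerVector hmm_viterbi(NumericMatrix logB, IntegerVector lens,
                          NumericVector pi0, NumericMatrix trans) {
  const int K = logB.ncol();
  const int Ttot = logB.nrow();
  IntegerVector path(Ttot);
  NumericMatrix logA(K, K);
  NumericVector logpi(K);
  for (int k = 0; k < K; ++k) {
    logpi[k] = std::log(std::max(pi0[k], 1e-300));
    for (int j = 0; j < K; ++j)
      logA(k, j) = std::log(std::max(trans(k, j), 1e-300));
  }
  int off = 0;
  for (int tr = 0; tr < lens.size(); ++tr) {
    const int T = lens[tr];
    std::vector<double> delta(T * K);
    std::vector<int> psi(T * K);
    for (int k = 0; k < K; ++k) delta[k] = logpi[k] + logB(off, k);
    for (int t = 1; t < T; ++t) {
      for (int k = 0; k < K; ++k) {
        double best = delta[(t - 1) * K] + logA(0, k);
        int arg = 0;
        for (int j = 1; j < K; ++j) {
          double v = delta[(t - 1) * K + j] + logA(j, k);
          if (v > best) { best = v; arg = j; }
        }
        delta[t * K + k] = best + logB(off + t, k);
        psi[t * K + k] = arg;
      }
    }
    int arg = 0;
    for (int k = 1; k < K; ++k)
      if (delta[(T - 1) * K + k] > delta[(T - 1) * K + arg]) arg = k;
    path[off + T - 1] = arg + 1;
    for (int t = T - 2; t >= 0; --t) {
      arg = psi[(t + 1) * K + arg];
      path[off + t] = arg + 1;
    }
    off += T;
  }
  return path;
}
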