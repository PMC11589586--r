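#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Layered HBD hidden Markov model. States carry per-Morgan exit rates R_k;
// across genetic distance d the chain stays with prob p = exp(-R_k d),
// else leaves and re-enters state l with prob M_l (re-entry allowed), so
// A(k,l) = p_k * 1{k==l} + (1 - p_k) * M_l.
// The stay probabilities P ((T-1) x S) are precomputed by the caller and
// shared across EM iterations; both passes exploit the rank-one jump
// structure and run in O(T * S).

// [[Rcpp::export]]
List hmm_forward_backward(const NumericMatrix& emis,
                          const NumericMatrix& P,
                          const NumericVector& M) {
  const int T = emis.nrow(), S = emis.ncol();
  if (T < 1) stop("zero-length observation sequence");
  if (M.size() != S) stop("one mixing coefficient per state required");
  if (P.nrow() != T - 1 || P.ncol() != S)
    stop("stay-probability matrix must be (T-1) x S");

  NumericMatrix alpha(T, S), beta(T, S), gamma(T, S);
  NumericVector cvec(T), entries(S);
  double loglik = 0.0;

  // forward
  double c0 = 0.0;
  for (int s = 0; s < S; ++s) { alpha(0, s) = emis(0, s) * M[s]; c0 += alpha(0, s); }
  if (c0 <= 0.0) stop("zero likelihood at marker 1");
  for (int s = 0; s < S; ++s) alpha(0, s) /= c0;
  cvec[0] = c0; loglik += std::log(c0);

  for (int t = 1; t < T; ++t) {
    double leave = 0.0;
    for (int s = 0; s < S; ++s)
      leave += alpha(t - 1, s) * (1.0 - P(t - 1, s));
    double ct = 0.0;
    for (int s = 0; s < S; ++s) {
      double a = emis(t, s) * (alpha(t - 1, s) * P(t - 1, s) + leave * M[s]);
      alpha(t, s) = a; ct += a;
    }
    if (ct <= 0.0) stop("zero likelihood at marker %d", t + 1);
    for (int s = 0; s < S; ++s) alpha(t, s) /= ct;
    cvec[t] = ct; loglik += std::log(ct);
  }

  // backward
  for (int s = 0; s < S; ++s) beta(T - 1, s) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    double pooled = 0.0;
    for (int s = 0; s < S; ++s)
      pooled += M[s] * emis(t + 1, s) * beta(t + 1, s);
    for (int s = 0; s < S; ++s)
      beta(t, s) = (P(t, s) * emis(t + 1, s) * beta(t + 1, s) +
                    (1.0 - P(t, s)) * pooled) / cvec[t + 1];
  }

  // posteriors and expected state-entry counts (for the EM update of M)
  for (int s = 0; s < S; ++s) {
    gamma(0, s) = alpha(0, s) * beta(0, s);
    entries[s] = gamma(0, s);
  }
  for (int t = 1; t < T; ++t) {
    double leave = 0.0;
    for (int s = 0; s < S; ++s)
      leave += alpha(t - 1, s) * (1.0 - P(t - 1, s));
    for (int s = 0; s < S; ++s) {
      gamma(t, s) = alpha(t, s) * beta(t, s);
      entries[s] += leave * M[s] * emis(t, s) * beta(t, s) / cvec[t];
    }
  }

  return List::create(_["gamma"] = gamma, _["loglik"] = loglik,
                      _["entries"] = entries);
}

// [[Rcpp::export]]
IntegerVector hmm_viterbi(const NumericMatrix& emis,
                          const NumericMatrix& P,
                          const NumericVector& M) {
  const int T = emis.nrow(), S = emis.ncol();
  if (T < 1) stop("zero-length observation sequence");
  if (P.nrow() != T - 1 || P.ncol() != S)
    stop("stay-probability matrix must be (T-1) x S");
  NumericMatrix delta(T, S);
  IntegerMatrix ptr(T, S);
  const double NEG_INF = -std::numeric_limits<double>::infinity();
  auto slog = [&](double x) { return x > 0.0 ? std::log(x) : NEG_INF; };

  for (int s = 0; s < S; ++s)
    delta(0, s) = slog(emis(0, s)) + slog(M[s]);

  for (int t = 1; t < T; ++t) {
    // A(k,l) = (1-p_k) M_l for k != l and p_l + (1-p_l) M_l for k == l.
    // Track the two best "leave" predecessors so the k != l maximum is
    // available even when the overall best one is l itself.
    double b1 = NEG_INF, b2 = NEG_INF; int k1 = 0, k2 = 0;
    for (int s = 0; s < S; ++s) {
      double v = delta(t - 1, s) + slog(1.0 - P(t - 1, s));
      if (v > b1)      { b2 = b1; k2 = k1; b1 = v; k1 = s; }
      else if (v > b2) { b2 = v; k2 = s; }
    }
    for (int s = 0; s < S; ++s) {
      double self = delta(t - 1, s) +
        slog(P(t - 1, s) + (1.0 - P(t - 1, s)) * M[s]);
      double bj = (k1 == s) ? b2 : b1;
      int    bk = (k1 == s) ? k2 : k1;
      double jump = bj + slog(M[s]);
      if (self >= jump) { delta(t, s) = self; ptr(t, s) = s; }
      else              { delta(t, s) = jump; ptr(t, s) = bk; }
      delta(t, s) += slog(emis(t, s));
    }
  }

  IntegerVector path(T);
  int best = 0;
  for (int s = 1; s < S; ++s) if (delta(T - 1, s) > delta(T - 1, best)) best = s;
  path[T - 1] = best;
  for (int t = T - 1; t > 0; --t) path[t - 1] = ptr(t, path[t]);
  for (int t = 0; t < T; ++t) path[t] += 1;  // 1-based state indices
  return path;
}
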