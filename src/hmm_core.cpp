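#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward pass for a two-state HMM with Gaussian emissions.
// Returns the log-likelihood, per-frame posteriors (gamma), and the summed
// pairwise posteriors (xi) needed for the Baum-Welch M-step.
// [[Rcpp::export(name = ".fb_two_state")]]
List fb_two_state(NumericVector obs, NumericVector mu, NumericVector sigma,
                  NumericMatrix A, NumericVector init) {
  const int T = obs.size();
  NumericMatrix B(T, 2), alpha(T, 2), beta(T, 2), gam(T, 2);
  NumericVector scale(T);

  for (int t = 0; t < T; ++t)
    for (int k = 0; k < 2; ++k)
      B(t, k) = R::dnorm(obs[t], mu[k], sigma[k], 0);

  double s = 0.0;
  for (int k = 0; k < 2; ++k) { alpha(0, k) = init[k] * B(0, k); s += alpha(0, k); }
  if (s <= 0) s = DBL_MIN;
  scale[0] = s;
  for (int k = 0; k < 2; ++k) alpha(0, k) /= s;

  for (int t = 1; t < T; ++t) {
    s = 0.0;
    for (int k = 0; k < 2; ++k) {
      double a = alpha(t - 1, 0) * A(0, k) + alpha(t - 1, 1) * A(1, k);
      alpha(t, k) = a * B(t, k);
      s += alpha(t, k);
    }
    if (s <= 0) s = DBL_MIN;
    scale[t] = s;
    for (int k = 0; k < 2; ++k) alpha(t, k) /= s;
  }

  beta(T - 1, 0) = beta(T - 1, 1) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int k = 0; k < 2; ++k) {
      double b = 0.0;
      for (int j = 0; j < 2; ++j) b += A(k, j) * B(t + 1, j) * beta(t + 1, j);
      beta(t, k) = b / scale[t + 1];
    }
  }

  NumericMatrix xi(2, 2);
  for (int t = 0; t < T; ++t) {
    double g = 0.0;
    for (int k = 0; k < 2; ++k) { gam(t, k) = alpha(t, k) * beta(t, k); g += gam(t, k); }
    for (int k = 0; k < 2; ++k) gam(t, k) /= g;
  }
  for (int t = 0; t < T - 1; ++t) {
    double denom = 0.0;
    double tmp[2][2];
    for (int k = 0; k < 2; ++k)
      for (int j = 0; j < 2; ++j) {
        tmp[k][j] = alpha(t, k) * A(k, j) * B(t + 1, j) * beta(t + 1, j);
        denom += tmp[k][j];
      }
    if (denom > 0)
      for (int k = 0; k < 2; ++k)
        for (int j = 0; j < 2; ++j) xi(k, j) += tmp[k][j] / denom;
  }

  double ll = 0.0;
  for (int t = 0; t < T; ++t) ll += std::log(scale[t]);

  return List::create(_["loglik"] = ll, _["gamma"] = gam, _["xi"] = xi);
}

// Viterbi decoding with a deterministic tie-break that prefers staying in the
// current state (hysteresis), so exact likelihood ties never produce spurious
// transitions. Returns 0-based state indices.
// [[Rcpp::export(name = ".viterbi_two_state")]]
IntegerVector viterbi_two_state(NumericVector obs, NumericVector mu,
                                NumericVector sigma, NumericMatrix A,
                                NumericVector init) {
  const int T = obs.size();
  NumericMatrix delta(T, 2);
  IntegerMatrix psi(T, 2);

  for (int k = 0; k < 2; ++k)
    delta(0, k) = std::log(std::max(init[k], DBL_MIN)) +
      R::dnorm(obs[0], mu[k], sigma[k], 1);

  for (int t = 1; t < T; ++t) {
    for (int k = 0; k < 2; ++k) {
      double best = R_NegInf; int arg = k;  // prefer self on ties
      double cand_self = delta(t - 1, k) + std::log(std::max(A(k, k), DBL_MIN));
      best = cand_self; arg = k;
      int other = 1 - k;
      double cand = delta(t - 1, other) + std::log(std::max(A(other, k), DBL_MIN));
      if (cand > best) { best = cand; arg = other; }
      delta(t, k) = best + R::dnorm(obs[t], mu[k], sigma[k], 1);
      psi(t, k) = arg;
    }
  }

  IntegerVector path(T);
  path[T - 1] = (delta(T - 1, 1) > delta(T - 1, 0)) ? 1 : 0;
  for (int t = T - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  return path;
}
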