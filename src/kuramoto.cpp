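#include <Rcpp.h>
using namespace Rcpp;

// Coupling drift for oscillator i: omega_i + K * sum_j sin(phi_j - phi_i),
// computed in O(n) via sum_j sin(phi_j - phi_i) = S cos(phi_i) - C sin(phi_i)
// with C = sum cos(phi_j), S = sum sin(phi_j). `normalize` divides by n
// (textbook Kuramoto variant); the printed model sums without 1/n.
static void kuramoto_drift(const std::vector<double>& phi,
                           const double* omega, double K, bool normalize,
                           std::vector<double>& f) {
  const int n = phi.size();
  double C = 0.0, S = 0.0;
  for (int i = 0; i < n; ++i) {
    C += std::cos(phi[i]);
    S += std::sin(phi[i]);
  }
  const double scale = normalize ? K / n : K;
  for (int i = 0; i < n; ++i)
    f[i] = omega[i] + scale * (S * std::cos(phi[i]) - C * std::sin(phi[i]));
}

// Stochastic Heun (predictor-corrector) integration of the noisy Kuramoto
// phase model. Noise draws use R's RNG so set.seed() governs reproducibility.
// Returns an (n_save x n) matrix of phases including the initial state.
// [[Rcpp::export]]
NumericMatrix simulate_kuramoto_cpp(NumericVector phi0, NumericVector omega,
                                    double K, double sigma, double dt,
                                    int n_steps, int save_every,
                                    bool normalize) {
  const int n = phi0.size();
  if (omega.size() != n) stop("omega and phi0 lengths differ");
  const int n_save = n_steps / save_every + 1;
  NumericMatrix out(n_save, n);
  std::vector<double> phi(phi0.begin(), phi0.end());
  std::vector<double> f0(n), f1(n), pred(n), dW(n);
  const double sqdt = std::sqrt(dt);

  for (int i = 0; i < n; ++i) out(0, i) = phi[i];
  RNGScope scope;
  int row = 1;
  for (int step = 1; step <= n_steps; ++step) {
    kuramoto_drift(phi, omega.begin(), K, normalize, f0);
    if (sigma > 0) {
      for (int i = 0; i < n; ++i) dW[i] = sigma * sqdt * norm_rand();
    } else {
      std::fill(dW.begin(), dW.end(), 0.0);
    }
    for (int i = 0; i < n; ++i) pred[i] = phi[i] + f0[i] * dt + dW[i];
    kuramoto_drift(pred, omega.begin(), K, normalize, f1);
    for (int i = 0; i < n; ++i)
      phi[i] += 0.5 * (f0[i] + f1[i]) * dt + dW[i];
    if (step % save_every == 0) {
      for (int i = 0; i < n; ++i) out(row, i) = phi[i];
      ++row;
    }
  }
  return out;
}
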