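#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Discrete-time spike sampler: inhomogeneous renewal process with a
// precomputed instantaneous rate (Hz per sample), modulated by a Normal-CDF
// refractory recovery with a hard floor, plus an optional transient rate
// boost ("burst") while the drive slope has recently exceeded a second
// threshold. Uses R's RNG so set.seed() governs reproducibility.

// [[Rcpp::export]]
NumericVector encode_sample_cpp(NumericVector rate_hz, NumericVector slope,
                                double dt_ms, double burst_gain,
                                double burst_threshold, double burst_dur_ms,
                                double recovery_mu_ms, double recovery_sigma_ms,
                                double floor_ms) {
  const int n = rate_hz.size();
  std::vector<double> out;
  out.reserve((size_t)(n * dt_ms * 1e-3 * 100.0) + 16);

  double t_last = -1e9;       // time of previous spike (ms)
  double burst_until = -1e9;  // burst boost active until this time (ms)
  RNGScope scope;

  for (int i = 0; i < n; ++i) {
    const double t = i * dt_ms;
    if (burst_gain > 0.0 && slope[i] > burst_threshold)
      burst_until = t + burst_dur_ms;

    double lambda = rate_hz[i];
    if (lambda <= 0.0) continue;
    if (t < burst_until) lambda *= (1.0 + burst_gain);

    const double since = t - t_last;
    if (since < floor_ms) continue;
    lambda *= R::pnorm(since, recovery_mu_ms, recovery_sigma_ms, 1, 0);

    const double p = lambda * dt_ms * 1e-3;
    if (unif_rand() < p) {
      out.push_back(t);
      t_last = t;
    }
  }
  return NumericVector(out.begin(), out.end());
}

// Renewal ISI sampler with a constant base hazard gated by the Normal-CDF
// recovery function (used for recovery-function parameter-recovery studies).

// [[Rcpp::export]]
NumericVector renewal_isis_cpp(int n_isi, double base_rate_hz, double dt_ms,
                               double recovery_mu_ms, double recovery_sigma_ms,
                               double floor_ms, double max_isi_ms) {
  NumericVector out(n_isi);
  RNGScope scope;
  const double p0 = base_rate_hz * dt_ms * 1e-3;
  for (int k = 0; k < n_isi; ++k) {
    double t = floor_ms;
    for (;;) {
      t += dt_ms;
      if (t > max_isi_ms) { t = max_isi_ms; break; }
      const double p = p0 * R::pnorm(t, recovery_mu_ms, recovery_sigma_ms, 1, 0);
      if (unif_rand() < p) break;
    }
    out[k] = t;
  }
  return out;
}
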