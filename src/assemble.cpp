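// Forward model assembly for the simulator: concentrations -> optical
// density (per-channel Beer-Lambert, identical to forward_mbll) -> drift,
// motion spikes, AR(1)+white measurement noise -> raw intensities.
// Uses R's RNG so a cohort is fully reproducible from its seed.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export(name = ".cpp_assemble_intensity")]]
List cpp_assemble_intensity(NumericMatrix hbo2, NumericMatrix hbr,
                            NumericVector dist_cm, NumericVector dpf,
                            NumericMatrix E, double drift_amp,
                            NumericVector spike_t, double spike_amp,
                            NumericVector spike_width_range,
                            double ar_coef, double ar_innov_sd,
                            double white_sd, NumericVector baseline_range,
                            double fs, double duration) {
  const int n = hbo2.nrow(), C = hbo2.ncol();
  List out(2);
  std::vector<double> od(n);
  for (int w = 0; w < 2; ++w) {
    NumericMatrix I(n, C);
    const double e1 = E(w, 0) * 1e-6, e2 = E(w, 1) * 1e-6;
    for (int c = 0; c < C; ++c) {
      const double path = dist_cm[c] * dpf[w];
      for (int i = 0; i < n; ++i)
        od[i] = (hbo2(i, c) * e1 + hbr(i, c) * e2) * path;
      // slow polynomial drift (linear + quadratic + cubic)
      double d1 = R::rnorm(0.0, drift_amp), d2 = R::rnorm(0.0, drift_amp),
             d3 = R::rnorm(0.0, drift_amp);
      if (drift_amp > 0) {
        for (int i = 0; i < n; ++i) {
          const double tt = (i / fs) / duration;
          od[i] += tt * (d1 + tt * (d2 + tt * d3));
        }
      }
      // transient motion spikes (Gaussian bumps, per-channel sign/size)
      for (int s = 0; s < spike_t.size(); ++s) {
        const double width = R::runif(spike_width_range[0],
                                      spike_width_range[1]);
        const double amp = spike_amp * R::rnorm(0.0, 1.0);
        if (amp == 0.0) continue;
        const double st = spike_t[s];
        int lo = (int)std::floor((st - 4.0 * width) * fs);
        int hi = (int)std::ceil((st + 4.0 * width) * fs);
        if (lo < 0) lo = 0;
        if (hi > n - 1) hi = n - 1;
        for (int i = lo; i <= hi; ++i) {
          const double z = (i / fs - st) / width;
          od[i] += amp * std::exp(-0.5 * z * z);
        }
      }
      // AR(1) + white measurement noise
      if (ar_innov_sd > 0 || white_sd > 0) {
        double ar = 0.0;
        for (int i = 0; i < n; ++i) {
          ar = ar_coef * ar + R::rnorm(0.0, ar_innov_sd);
          od[i] += ar + R::rnorm(0.0, white_sd);
        }
      }
      const double base = R::runif(baseline_range[0], baseline_range[1]);
      for (int i = 0; i < n; ++i) I(i, c) = base * std::exp(-od[i]);
    }
    out[w] = I;
  }
  out.names() = CharacterVector::create("w690", "w830");
  return out;
}
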