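#include <Rcpp.h>
#include <complex>
using namespace Rcpp;

// 4th-order all-pole digital gammatone: four cascaded complex one-pole
// filters with pole r*exp(i*w_c), r = exp(-2*pi*bw/fs). The impulse
// response envelope is ~ n^3 r^n, the discrete counterpart of the analog
// gammatone t^3 exp(-2*pi*b*t). The real part of the complex output is the
// filtered signal; the gain is normalized analytically so the response at
// the center frequency is unity.

// [[Rcpp::export]]
NumericVector gammatone_filter_cpp(NumericVector x, double cf, double bw,
                                   double fs) {
  const int n = x.size();
  const double wc = 2.0 * M_PI * cf / fs;
  const double lambda = 2.0 * M_PI * bw / fs;
  const std::complex<double> p = std::exp(std::complex<double>(-lambda, wc));
  // positive-frequency branch gain at cf: H(wc) = 1 / (1 - p e^{-i wc})^4;
  // the real output keeps half of it, hence the factor 2.
  const std::complex<double> d = 1.0 - p * std::exp(std::complex<double>(0.0, -wc));
  const double norm = 2.0 * std::pow(std::abs(d), 4.0);

  std::vector<std::complex<double>> y(n);
  for (int i = 0; i < n; ++i) y[i] = x[i];
  for (int s = 0; s < 4; ++s) {
    std::complex<double> state(0.0, 0.0);
    for (int i = 0; i < n; ++i) {
      state = y[i] + p * state;
      y[i] = state;
    }
  }
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = norm * y[i].real();
  return out;
}

// Per-channel RMS of the gammatone filterbank output for one signal:
// returns a vector of length cfs.size().

// [[Rcpp::export]]
NumericVector excitation_rms_cpp(NumericVector x, NumericVector cfs,
                                 NumericVector bws, double fs) {
  const int n = x.size();
  const int m = cfs.size();
  NumericVector out(m);
  for (int c = 0; c < m; ++c) {
    const double wc = 2.0 * M_PI * cfs[c] / fs;
    const double lambda = 2.0 * M_PI * bws[c] / fs;
    const std::complex<double> p = std::exp(std::complex<double>(-lambda, wc));
    const std::complex<double> d =
        1.0 - p * std::exp(std::complex<double>(0.0, -wc));
    const double norm = 2.0 * std::pow(std::abs(d), 4.0);
    std::vector<std::complex<double>> y(n);
    for (int i = 0; i < n; ++i) y[i] = x[i];
    for (int s = 0; s < 4; ++s) {
      std::complex<double> state(0.0, 0.0);
      for (int i = 0; i < n; ++i) {
        state = y[i] + p * state;
        y[i] = state;
      }
    }
    double acc = 0.0;
    for (int i = 0; i < n; ++i) {
      const double v = norm * y[i].real();
      acc += v * v;
    }
    out[c] = std::sqrt(acc / n);
  }
  return out;
}
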