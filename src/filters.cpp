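#include <Rcpp.h>
#include <complex>
using namespace Rcpp;

// Cascade of `order` identical complex one-pole resonators per channel
// (all-pole gammatone). Each channel's complex output is scaled by a complex
// gain (unit magnitude response at the center frequency plus a phase
// rotation), delayed by an integer number of samples, and the real part
// doubled to recover the real bandpass signal.
// [[Rcpp::export]]
NumericMatrix gammatone_cascade(NumericVector x, NumericVector pole_re,
                                NumericVector pole_im, NumericVector gain_re,
                                NumericVector gain_im, IntegerVector delay,
                                int order) {
  const int n = x.size();
  const int K = pole_re.size();
  NumericMatrix out(n, K);
  for (int k = 0; k < K; ++k) {
    const std::complex<double> a(pole_re[k], pole_im[k]);
    const std::complex<double> g(gain_re[k], gain_im[k]);
    const int d = delay[k];
    std::vector<std::complex<double> > state(order, std::complex<double>(0.0, 0.0));
    double *col = &out(0, k);
    for (int i = 0; i < n; ++i) {
      std::complex<double> v(x[i], 0.0);
      for (int s = 0; s < order; ++s) {
        v += a * state[s];
        state[s] = v;
      }
      const int j = i + d;
      if (j < n) col[j] = 2.0 * (g * v).real();
    }
  }
  return out;
}

// First-order exponential smoother applied down each column:
//   y[i] = alpha * x[i] + (1 - alpha) * y[i-1],  y[-1] = 0.
// [[Rcpp::export]]
NumericMatrix ema_columns(NumericMatrix x, double alpha) {
  const int n = x.nrow(), K = x.ncol();
  NumericMatrix out(n, K);
  const double beta = 1.0 - alpha;
  for (int k = 0; k < K; ++k) {
    double acc = 0.0;
    for (int i = 0; i < n; ++i) {
      acc = alpha * x(i, k) + beta * acc;
      out(i, k) = acc;
    }
  }
  return out;
}
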