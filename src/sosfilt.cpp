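#include <Rcpp.h>
using namespace Rcpp;

// Cascaded biquad (second-order-sections) filter, direct form II transposed.
// sos: n_sections x 6 matrix (b0 b1 b2 a0 a1 a2), a0 == 1 assumed (designs
// normalise). States start at the section's step-input steady state scaled
// by the first sample, so a constant signal passes without any transient
// (the filtfilt convention).
// [[Rcpp::export]]
NumericVector sosfilt_cpp(NumericMatrix sos, NumericVector x) {
  int ns = sos.nrow();
  int n = x.size();
  NumericVector y = clone(x);
  for (int s = 0; s < ns; ++s) {
    double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
    double a1 = sos(s, 4), a2 = sos(s, 5);
    double den = 1.0 + a1 + a2;
    double hdc = (den != 0.0) ? (b0 + b1 + b2) / den : 0.0;
    double z1 = y[0] * (hdc - b0);
    double z2 = y[0] * (b2 - a2 * hdc);
    for (int i = 0; i < n; ++i) {
      double xi = y[i];
      double yi = b0 * xi + z1;
      z1 = b1 * xi - a1 * yi + z2;
      z2 = b2 * xi - a2 * yi;
      y[i] = yi;
    }
  }
  return y;
}
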