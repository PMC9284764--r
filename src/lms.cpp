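#include <Rcpp.h>
using namespace Rcpp;

// Two-weight LMS adaptive noise canceller with a quadrature (sin/cos)
// reference at a fixed frequency. The per-sample weight recursion cannot be
// vectorized in R, so it lives here.
//
// x:    observed signal (desired + sinusoidal interference)
// s, c: unit-amplitude sin/cos reference at the target frequency
// mu:   adaptation step (reference power is 0.5, so mu << 4 is stable)
//
// Returns the error signal e = x - w1*s - w2*c (the cleaned signal).
// Throws if the weight norm explodes (divergence).
// [[Rcpp::export]]
NumericVector lms_cancel_cpp(NumericVector x, NumericVector s,
                             NumericVector c, double mu) {
  int n = x.size();
  NumericVector e(n);
  double w1 = 0.0, w2 = 0.0;
  for (int i = 0; i < n; ++i) {
    double yhat = w1 * s[i] + w2 * c[i];
    double err = x[i] - yhat;
    e[i] = err;
    w1 += 2.0 * mu * err * s[i];
    w2 += 2.0 * mu * err * c[i];
    if (w1 * w1 + w2 * w2 > 1e16)
      stop("LMS canceller diverged (weight norm explosion); reduce lms_step");
  }
  return e;
}
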