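#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Two-parameter Weibull maximum likelihood via the profile equation in the
// shape k. With y = x / max(x) (scale invariance keeps powers bounded):
//   g(k) = 1/k + mean(log y) - sum(y^k log y) / sum(y^k)
// g is strictly decreasing in k with a unique root for non-degenerate
// samples; solved by safeguarded Newton (bisection fallback on a bracket).
// The scale then is lambda = max(x) * (mean(y^k))^(1/k).

static void profile_gd(const std::vector<double>& y,
                       const std::vector<double>& logy,
                       double mlog, double k, double& g, double& dg) {
  double s0 = 0.0, s1 = 0.0, s2 = 0.0;
  const size_t n = y.size();
  for (size_t i = 0; i < n; ++i) {
    double yk = std::pow(y[i], k);
    double t = yk * logy[i];
    s0 += yk;
    s1 += t;
    s2 += t * logy[i];
  }
  g = 1.0 / k + mlog - s1 / s0;
  dg = -1.0 / (k * k) - (s2 * s0 - s1 * s1) / (s0 * s0);
}

static bool weibull_mle_core(const std::vector<double>& x,
                             double init, double& shape, double& scale) {
  const size_t n = x.size();
  if (n < 2) return false;
  double xmax = 0.0;
  for (size_t i = 0; i < n; ++i) {
    if (!(x[i] > 0.0)) return false;
    if (x[i] > xmax) xmax = x[i];
  }
  std::vector<double> y(n), logy(n);
  double mlog = 0.0;
  bool constant = true;
  for (size_t i = 0; i < n; ++i) {
    y[i] = x[i] / xmax;
    logy[i] = std::log(y[i]);
    mlog += logy[i];
    if (x[i] != x[0]) constant = false;
  }
  if (constant) return false; // zero variance: no finite MLE
  mlog /= n;

  double lo = 1e-3, hi = 1e4; // g(lo) > 0 for any non-degenerate sample
  double k = (init > lo && init < hi) ? init : 1.0;
  double g, dg;
  bool ok = false;
  for (int it = 0; it < 100; ++it) {
    profile_gd(y, logy, mlog, k, g, dg);
    if (std::fabs(g) < 1e-12) { ok = true; break; }
    if (g > 0.0) lo = k; else hi = k;
    double knew = (dg < 0.0) ? k - g / dg : lo;
    if (!(knew > lo && knew < hi)) knew = 0.5 * (lo + hi);
    if (std::fabs(knew - k) < 1e-13 * k) { k = knew; ok = true; break; }
    k = knew;
    if (hi - lo < 1e-13 * hi) { ok = true; break; }
  }
  if (!ok || k <= 1e-3 || k >= 1e4 * 0.999) return false;
  shape = k;
  double s0 = 0.0;
  for (size_t i = 0; i < n; ++i) s0 += std::pow(y[i], shape);
  scale = xmax * std::pow(s0 / n, 1.0 / shape);
  return R_finite(shape) && R_finite(scale) && shape > 0 && scale > 0;
}

// [[Rcpp::export]]
List weibull_mle_cpp(NumericVector x) {
  std::vector<double> xv(x.begin(), x.end());
  double shape = NA_REAL, scale = NA_REAL;
  bool ok = weibull_mle_core(xv, 1.0, shape, scale);
  return List::create(_["shape"] = ok ? shape : NA_REAL,
                      _["scale"] = ok ? scale : NA_REAL,
                      _["converged"] = ok);
}

// Nonparametric bootstrap of the shape estimate: B resamples with
// replacement, MLE refit on each (warm-started at the full-sample
// estimate). Uses R's RNG (controlled by set.seed() on the R side).
// Resamples where the MLE degenerates return NA.
// [[Rcpp::export]]
NumericVector weibull_shape_boot_cpp(NumericVector x, int B) {
  const int n = x.size();
  NumericVector out(B, NA_REAL);
  std::vector<double> xv(x.begin(), x.end());
  double shape0 = 1.0, scale0;
  weibull_mle_core(xv, 1.0, shape0, scale0);
  std::vector<double> resample(n);
  RNGScope scope;
  for (int b = 0; b < B; ++b) {
    for (int i = 0; i < n; ++i) {
      int j = (int)(unif_rand() * n);
      if (j == n) j = n - 1;
      resample[i] = x[j];
    }
    double shape, scale;
    if (weibull_mle_core(resample, shape0, shape, scale)) out[b] = shape;
  }
  return out;
}
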