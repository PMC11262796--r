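#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Hit-and-run random walk over the polytope {z : lo <= C z <= hi}.
// Directions are isotropic Gaussian; one step moves to a uniform point on the
// chord through the current point. Uses R's RNG so draws are reproducible
// under set.seed(). Bounds with |value| >= 1e29 are treated as infinite.
// Returns n_keep rows of z, taken every `thin` steps after `warmup` steps.
// [[Rcpp::export(name = ".hit_and_run_core")]]
NumericMatrix hit_and_run_core(NumericMatrix C, NumericVector lo, NumericVector hi,
                               NumericVector z0, int n_keep, int thin, int warmup) {
  const int m = C.nrow(), d = C.ncol();
  const double INFB = 1e29;
  std::vector<double> z(z0.begin(), z0.end());
  std::vector<double> s(m), a(m), u(d);
  NumericMatrix out(n_keep, d);

  auto refresh_s = [&]() {
    for (int i = 0; i < m; ++i) {
      double acc = 0.0;
      for (int k = 0; k < d; ++k) acc += C(i, k) * z[k];
      s[i] = acc;
    }
  };
  refresh_s();

  const long total = (long)warmup + (long)n_keep * (long)thin;
  int kept = 0;
  for (long step = 0; step < total && kept < n_keep; ++step) {
    // random unit direction
    double nrm = 0.0;
    for (int k = 0; k < d; ++k) { u[k] = norm_rand(); nrm += u[k] * u[k]; }
    nrm = std::sqrt(nrm);
    if (nrm < 1e-300) continue;
    for (int k = 0; k < d; ++k) u[k] /= nrm;

    // chord limits along u
    double alo = -std::numeric_limits<double>::infinity();
    double ahi = std::numeric_limits<double>::infinity();
    for (int i = 0; i < m; ++i) {
      double ai = 0.0;
      for (int k = 0; k < d; ++k) ai += C(i, k) * u[k];
      a[i] = ai;
      if (std::fabs(ai) < 1e-12) continue;
      double to_hi = (hi[i] >= INFB) ? std::numeric_limits<double>::infinity()
                                     : (hi[i] - s[i]) / ai;
      double to_lo = (lo[i] <= -INFB) ? -std::numeric_limits<double>::infinity()
                                      : (lo[i] - s[i]) / ai;
      if (ai > 0) {
        if (to_hi < ahi) ahi = to_hi;
        if (to_lo > alo) alo = to_lo;
      } else {  // moving decreases s[i]: lo gives the upper alpha limit
        double lim_hi = (lo[i] <= -INFB) ? std::numeric_limits<double>::infinity()
                                         : (lo[i] - s[i]) / ai;
        double lim_lo = (hi[i] >= INFB) ? -std::numeric_limits<double>::infinity()
                                        : (hi[i] - s[i]) / ai;
        if (lim_hi < ahi) ahi = lim_hi;
        if (lim_lo > alo) alo = lim_lo;
      }
    }
    double alpha = 0.0;
    if (std::isfinite(alo) && std::isfinite(ahi) && ahi > alo) {
      alpha = alo + unif_rand() * (ahi - alo);
    }
    if (alpha != 0.0) {
      for (int k = 0; k < d; ++k) z[k] += alpha * u[k];
      for (int i = 0; i < m; ++i) s[i] += alpha * a[i];
    }
    if (step % 1024 == 1023) refresh_s();  // kill numerical drift

    if (step >= warmup && ((step - warmup + 1) % thin == 0)) {
      for (int k = 0; k < d; ++k) out(kept, k) = z[k];
      ++kept;
    }
  }
  return out;
}
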