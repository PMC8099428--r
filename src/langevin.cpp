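#include <Rcpp.h>
using namespace Rcpp;

// Overdamped (Brownian) Euler-Maruyama integration on a sum-of-inverted-
// Gaussians or harmonic potential. Uses R's RNG so set.seed() governs the
// trajectory bit-for-bit. form: 0 = gaussian wells, 1 = harmonic (depths[0]
// holds the spring constant in kT/nm^2, centers row 0 the minimum).
//
// x_{t+1} = x_t - (dt/gamma) * gradU(x_t) + sqrt(2*kT*dt/gamma) * xi

static inline void grad_u(int form, const NumericMatrix &centers,
                          const NumericVector &depths,
                          const NumericVector &widths,
                          const NumericVector &confine_center,
                          double confine_radius, double confine_k,
                          const double *x, int d, double *g) {
  for (int j = 0; j < d; ++j) g[j] = 0.0;
  if (form == 1) {
    double kappa = depths[0];
    for (int j = 0; j < d; ++j) g[j] = kappa * (x[j] - centers(0, j));
    return;
  }
  int m = centers.nrow();
  for (int i = 0; i < m; ++i) {
    double r2 = 0.0;
    for (int j = 0; j < d; ++j) {
      double dx = x[j] - centers(i, j);
      r2 += dx * dx;
    }
    double w2 = widths[i] * widths[i];
    double e = depths[i] * std::exp(-r2 / (2.0 * w2)) / w2;
    for (int j = 0; j < d; ++j) g[j] += e * (x[j] - centers(i, j));
  }
  if (confine_k > 0.0) {
    // flat-bottom harmonic wall per coordinate
    for (int j = 0; j < d; ++j) {
      double dxc = x[j] - confine_center[j];
      double exc = std::fabs(dxc) - confine_radius;
      if (exc > 0.0) g[j] += confine_k * ((dxc > 0) ? exc : -exc);
    }
  }
}

// [[Rcpp::export]]
List langevin_cpp(int form, NumericMatrix centers, NumericVector depths,
                  NumericVector widths, NumericVector confine_center,
                  double confine_radius, double confine_k, double kT,
                  double friction, double dt, int n_steps, NumericVector x0,
                  double min_width) {
  int d = x0.size();
  NumericMatrix out(n_steps, d);
  std::vector<double> x(d), g(d);
  for (int j = 0; j < d; ++j) x[j] = x0[j];
  double drift = dt / friction;
  double noise = std::sqrt(2.0 * kT * dt / friction);
  bool step_warn = false;
  double max_step = 10.0 * min_width;
  RNGScope scope;
  for (int t = 0; t < n_steps; ++t) {
    grad_u(form, centers, depths, widths, confine_center,
           confine_radius, confine_k, x.data(), d, g.data());
    double step2 = 0.0;
    for (int j = 0; j < d; ++j) {
      if (!R_finite(g[j])) {
        return List::create(_["error"] = true, _["step"] = t + 1,
                            _["position"] = NumericVector(x.begin(), x.end()));
      }
      double dxj = -drift * g[j] + noise * norm_rand();
      step2 += dxj * dxj;
      x[j] += dxj;
      out(t, j) = x[j];
    }
    if (!step_warn && std::sqrt(step2) > max_step) step_warn = true;
  }
  return List::create(_["error"] = false, _["positions"] = out,
                      _["step_warning"] = step_warn);
}
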