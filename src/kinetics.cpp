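#include <Rcpp.h>
using namespace Rcpp;

// Forward-Euler trajectory of the regulator-driven expression model
//   dz/dt = k1 * sigmoid(b + sum_r w_r * y_r(t)) - k2 * z
// reg_fine holds regulator values on the fine integration grid (step dt),
// one column per regulator; the full fine-grid trajectory is returned.
// [[Rcpp::export]]
NumericVector euler_kinetic_cpp(double k1, double k2, double b,
                                NumericVector w, double z0,
                                NumericMatrix reg_fine, double dt) {
  const int n = reg_fine.nrow();
  const int nr = reg_fine.ncol();
  NumericVector z(n);
  z[0] = z0;
  for (int t = 0; t + 1 < n; ++t) {
    double s = b;
    for (int r = 0; r < nr; ++r) s += w[r] * reg_fine(t, r);
    const double sig = 1.0 / (1.0 + std::exp(-s));
    z[t + 1] = z[t] + dt * (k1 * sig - k2 * z[t]);
  }
  return z;
}

static double kinetic_sse(const NumericVector& par, double z0,
                          const NumericMatrix& reg_fine, double dt,
                          const IntegerVector& obs_idx,
                          const NumericVector& obs) {
  const int n = reg_fine.nrow();
  const int nr = reg_fine.ncol();
  const double k1 = par[0], k2 = par[1], b = par[2];
  // extended-precision accumulator, matching R's sum()
  long double sse = 0.0;
  double z = z0;
  int next = 0;
  for (int t = 0; t < n; ++t) {
    if (next < obs_idx.size() && obs_idx[next] - 1 == t) {
      const double d = z - obs[next];
      sse += d * d;
      ++next;
    }
    if (t + 1 < n) {
      double s = b;
      for (int r = 0; r < nr; ++r) s += par[3 + r] * reg_fine(t, r);
      const double sig = 1.0 / (1.0 + std::exp(-s));
      z += dt * (k1 * sig - k2 * z);
    }
  }
  return (double)sse;
}

// Simulated annealing over the kinetic parameters (k1, k2, b, w_1..w_R),
// z0 held fixed. Uses R's RNG so a set.seed() in R makes the run
// reproducible, with the same draw order as the reference annealer written
// in R: init = lower + runif(npar) * width; per iteration rnorm(npar)
// proposal then one runif(1) acceptance draw; geometric cooling.
// [[Rcpp::export]]
List sa_fit_kinetic_cpp(NumericMatrix reg_fine, NumericVector obs,
                        IntegerVector obs_idx, double dt, double z0,
                        NumericVector lower, NumericVector upper,
                        int n_iter, double t0, double cooling,
                        NumericVector prop_sd) {
  const int npar = lower.size();
  NumericVector cur(npar), prop(npar), best(npar);
  for (int j = 0; j < npar; ++j)
    cur[j] = lower[j] + R::runif(0.0, 1.0) * (upper[j] - lower[j]);
  double f_cur = kinetic_sse(cur, z0, reg_fine, dt, obs_idx, obs);
  best = clone(cur);
  double f_best = f_cur;
  double temp = t0;
  for (int it = 0; it < n_iter; ++it) {
    for (int j = 0; j < npar; ++j) {
      double x = cur[j] + R::rnorm(0.0, 1.0) * prop_sd[j];
      if (x < lower[j]) x = lower[j];
      if (x > upper[j]) x = upper[j];
      prop[j] = x;
    }
    const double f_prop = kinetic_sse(prop, z0, reg_fine, dt, obs_idx, obs);
    const double u = R::runif(0.0, 1.0);
    if (f_prop <= f_cur || u < std::exp(-(f_prop - f_cur) / temp)) {
      cur = clone(prop);
      f_cur = f_prop;
      if (f_cur < f_best) { best = clone(cur); f_best = f_cur; }
    }
    temp *= cooling;
  }
  return List::create(_["par"] = best, _["sse"] = f_best);
}
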