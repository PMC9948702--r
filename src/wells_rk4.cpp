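#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fixed-step 4th-order Runge-Kutta integration of the within-well system
//   dx_i/dt = x_i * r_i * (1 - sum_k x_k / K)        (bracket[w] = true)
//   dx_i/dt = x_i * r_i                              (bracket[w] = false)
// for a batch of independent wells. x0 and rates are n_wells x n_strains;
// bracket selects, per well, whether the logistic term applies (non-viable
// wells may optionally decay purely exponentially).
//
// The last step is shortened so the total duration is exactly t. A density
// driven below -1e-9*K signals instability of the step size; tiny negative
// round-off is clamped to zero.
// [[Rcpp::export]]
NumericMatrix wells_rk4(NumericMatrix x0, NumericMatrix rates, double K,
                        double t, double dt, LogicalVector bracket) {
  const int nw = x0.nrow();
  const int ns = x0.ncol();
  if (rates.nrow() != nw || rates.ncol() != ns)
    stop("`rates` must have the same shape as the state matrix");
  if (bracket.size() != nw)
    stop("`bracket` must have one entry per well");
  if (K <= 0) stop("`K` must be > 0");
  if (dt <= 0) stop("`dt` must be > 0");
  NumericMatrix out = clone(x0);
  if (t <= 0) return out;

  const int nstep = (int)std::ceil(t / dt - 1e-9);
  const double neg_tol = -1e-9 * K;
  std::vector<double> y(ns), k1(ns), k2(ns), k3(ns), k4(ns), tmp(ns);

  for (int w = 0; w < nw; ++w) {
    for (int i = 0; i < ns; ++i) y[i] = out(w, i);
    const bool br = bracket[w];
    double remaining = t;
    for (int s = 0; s < nstep; ++s) {
      const double h = (remaining < dt) ? remaining : dt;
      remaining -= h;

      auto deriv = [&](const std::vector<double>& v, std::vector<double>& d) {
        double fac = 1.0;
        if (br) {
          double tot = 0.0;
          for (int i = 0; i < ns; ++i) tot += v[i];
          fac = 1.0 - tot / K;
        }
        for (int i = 0; i < ns; ++i) d[i] = v[i] * rates(w, i) * fac;
      };

      deriv(y, k1);
      for (int i = 0; i < ns; ++i) tmp[i] = y[i] + 0.5 * h * k1[i];
      deriv(tmp, k2);
      for (int i = 0; i < ns; ++i) tmp[i] = y[i] + 0.5 * h * k2[i];
      deriv(tmp, k3);
      for (int i = 0; i < ns; ++i) tmp[i] = y[i] + h * k3[i];
      deriv(tmp, k4);
      for (int i = 0; i < ns; ++i) {
        y[i] += h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
        if (y[i] < 0.0) {
          if (y[i] < neg_tol)
            stop("integration instability: density went negative; use a smaller `dt`");
          y[i] = 0.0;
        }
      }
    }
    for (int i = 0; i < ns; ++i) out(w, i) = y[i];
  }
  return out;
}
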