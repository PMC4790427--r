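#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Piecewise-linear interpolation of the plasma input enrichment,
// constant extrapolation beyond the table.
static double interp_fe(double t, const NumericVector& tt,
                        const NumericVector& ff) {
  const int n = tt.size();
  if (t <= tt[0]) return ff[0];
  if (t >= tt[n - 1]) return ff[n - 1];
  int lo = 0, hi = n - 1;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (tt[mid] <= t) lo = mid; else hi = mid;
  }
  double w = (t - tt[lo]) / (tt[hi] - tt[lo]);
  return ff[lo] + w * (ff[hi] - ff[lo]);
}

struct CumomerRHS {
  int n, m;                      // states, driven slots
  const int* tgt; const double* k; const int* s1; const int* s2;
  int nterms;
  const double* outrate;         // per state, 1/min times conc
  const double* conc;
  const int* da; const int* db;  // driven exponents
  double na;
  const NumericVector* in_t; const NumericVector* in_fe;
  mutable std::vector<double> x; // [states, driven, 1.0]

  void operator()(double t, const double* y, double* dy) const {
    double fe = interp_fe(t, *in_t, *in_fe);
    for (int i = 0; i < n; ++i) x[i] = y[i];
    for (int j = 0; j < m; ++j)
      x[n + j] = std::pow(fe, da[j]) * std::pow(na, db[j]);
    x[n + m] = 1.0;
    for (int i = 0; i < n; ++i) dy[i] = -outrate[i] * y[i];
    for (int q = 0; q < nterms; ++q)
      dy[tgt[q]] += k[q] * x[s1[q]] * x[s2[q]];
    for (int i = 0; i < n; ++i) dy[i] /= conc[i];
  }
};

// Dormand-Prince 5(4) adaptive integrator over a fixed output grid.
// Index convention for s1/s2: 0..n-1 states, n..n+m-1 driven slots,
// n+m the constant slot (value 1).
// [[Rcpp::export]]
NumericMatrix rk45_integrate(NumericVector y0, NumericVector out_times,
                             IntegerVector t_tgt, NumericVector t_k,
                             IntegerVector t_s1, IntegerVector t_s2,
                             NumericVector outrate, NumericVector conc,
                             IntegerVector d_a, IntegerVector d_b,
                             NumericVector in_t, NumericVector in_fe,
                             double na, double rtol, double atol,
                             int max_steps) {
  const int n = y0.size();
  const int nt = out_times.size();
  NumericMatrix out(nt, n);

  CumomerRHS f;
  f.n = n; f.m = d_a.size();
  f.tgt = t_tgt.begin(); f.k = t_k.begin();
  f.s1 = t_s1.begin(); f.s2 = t_s2.begin();
  f.nterms = t_tgt.size();
  f.outrate = outrate.begin(); f.conc = conc.begin();
  f.da = d_a.begin(); f.db = d_b.begin();
  f.na = na; f.in_t = &in_t; f.in_fe = &in_fe;
  f.x.assign(n + f.m + 1, 0.0);

  // Dormand-Prince tableau
  static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5,
                      c5 = 8.0 / 9;
  static const double a21 = 1.0 / 5;
  static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
  static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
  static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                      a53 = 64448.0 / 6561, a54 = -212.0 / 729;
  static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                      a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                      a65 = -5103.0 / 18656;
  static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                      b5 = -2187.0 / 6784, b6 = 11.0 / 84;
  static const double e1 = 35.0 / 384 - 5179.0 / 57600,
                      e3 = 500.0 / 1113 - 7571.0 / 16695,
                      e4 = 125.0 / 192 - 393.0 / 640,
                      e5 = -2187.0 / 6784 + 92097.0 / 339200,
                      e6 = 11.0 / 84 - 187.0 / 2100,
                      e7 = -1.0 / 40;

  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> k1(n), k2(n), k3(n), k4(n), k5(n), k6(n), k7(n),
      ytmp(n), ynew(n);

  double t = out_times[0];
  for (int i = 0; i < n; ++i) out(0, i) = y[i];

  double h = (out_times[nt - 1] - t) / 100.0;
  if (h <= 0) stop("output times must be increasing");
  const double hmin = 1e-12 * (out_times[nt - 1] - out_times[0]);
  int steps = 0;
  bool fresh_k1 = false;

  for (int row = 1; row < nt; ++row) {
    double tend = out_times[row];
    while (t < tend) {
      if (++steps > max_steps)
        stop("integrator exceeded max_steps at t = %f", t);
      if (h > tend - t) h = tend - t;
      if (h < hmin) stop("integrator step size underflow at t = %f", t);

      if (!fresh_k1) f(t, y.data(), k1.data());
      for (int i = 0; i < n; ++i) ytmp[i] = y[i] + h * a21 * k1[i];
      f(t + c2 * h, ytmp.data(), k2.data());
      for (int i = 0; i < n; ++i)
        ytmp[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
      f(t + c3 * h, ytmp.data(), k3.data());
      for (int i = 0; i < n; ++i)
        ytmp[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
      f(t + c4 * h, ytmp.data(), k4.data());
      for (int i = 0; i < n; ++i)
        ytmp[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] +
                              a54 * k4[i]);
      f(t + c5 * h, ytmp.data(), k5.data());
      for (int i = 0; i < n; ++i)
        ytmp[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                              a64 * k4[i] + a65 * k5[i]);
      f(t + h, ytmp.data(), k6.data());
      for (int i = 0; i < n; ++i)
        ynew[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] +
                              b5 * k5[i] + b6 * k6[i]);
      f(t + h, ynew.data(), k7.data());

      double err = 0.0;
      for (int i = 0; i < n; ++i) {
        double ei = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] +
                         e5 * k5[i] + e6 * k6[i] + e7 * k7[i]);
        double sc = atol + rtol * std::max(std::fabs(y[i]),
                                           std::fabs(ynew[i]));
        double r = ei / sc;
        err += r * r;
      }
      err = std::sqrt(err / n);
      if (!std::isfinite(err))
        stop("non-finite state encountered at t = %f", t);

      if (err <= 1.0) {
        t += h;
        y.swap(ynew);
        k1.swap(k7);          // FSAL
        fresh_k1 = true;
      } else {
        fresh_k1 = false;
      }
      double fac = 0.9 * std::pow(std::max(err, 1e-10), -0.2);
      if (fac < 0.2) fac = 0.2;
      if (fac > 5.0) fac = 5.0;
      h *= fac;
    }
    for (int i = 0; i < n; ++i) out(row, i) = y[i];
  }
  return out;
}
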