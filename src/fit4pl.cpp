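#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Four-parameter logistic on log10 dose s:
//   y(s) = b + (t - b) * u,   u = 1 / (1 + 10^{h (m - s)})
// with m = log10(EC50) and h > 0 the Hill slope. As s -> inf, y -> t (top).
// Note u (1 - u) = rho / (1 + rho)^2, used for stable derivatives.

static const double LN10 = 2.302585092994045684;

static inline double logistic_u(double h, double m, double s) {
  double a = h * (m - s) * LN10;
  if (a > 0) { double e = std::exp(-a); return e / (1.0 + e); }
  return 1.0 / (1.0 + std::exp(a));
}

// Profiled ("variable projection") RSS: for fixed (m, h) the model is linear
// in (b, t). The slope of y on u is clamped at 0 so that top >= bottom,
// i.e. response never decreases with dose.
static double varpro_rss(const double* s, const double* y, int n,
                         double m, double h, double* b_out, double* t_out) {
  double su = 0, sy = 0, suu = 0, suy = 0;
  std::vector<double> u(n);
  for (int i = 0; i < n; ++i) {
    u[i] = logistic_u(h, m, s[i]);
    su += u[i]; sy += y[i]; suu += u[i] * u[i]; suy += u[i] * y[i];
  }
  double ubar = su / n, ybar = sy / n;
  double var_u = suu - n * ubar * ubar;
  double cov_uy = suy - n * ubar * ybar;
  double beta = (var_u > 1e-12) ? cov_uy / var_u : 0.0;
  if (beta < 0.0) beta = 0.0;
  double b0 = ybar - beta * ubar;
  double rss = 0;
  for (int i = 0; i < n; ++i) {
    double r = b0 + beta * u[i] - y[i];
    rss += r * r;
  }
  *b_out = b0; *t_out = b0 + beta;
  return rss;
}

// Solve 4x4 linear system A x = rhs in place (Gaussian elimination with
// partial pivoting). Returns false if singular.
static bool solve4(double A[4][4], double rhs[4], double x[4]) {
  int piv[4] = {0, 1, 2, 3};
  for (int col = 0; col < 4; ++col) {
    int best = col;
    for (int r = col + 1; r < 4; ++r)
      if (std::fabs(A[r][col]) > std::fabs(A[best][col])) best = r;
    if (std::fabs(A[best][col]) < 1e-300) return false;
    if (best != col) {
      for (int c = 0; c < 4; ++c) std::swap(A[col][c], A[best][c]);
      std::swap(rhs[col], rhs[best]);
      std::swap(piv[col], piv[best]);
    }
    for (int r = col + 1; r < 4; ++r) {
      double f = A[r][col] / A[col][col];
      for (int c = col; c < 4; ++c) A[r][c] -= f * A[col][c];
      rhs[r] -= f * rhs[col];
    }
  }
  for (int r = 3; r >= 0; --r) {
    double v = rhs[r];
    for (int c = r + 1; c < 4; ++c) v -= A[r][c] * x[c];
    x[r] = v / A[r][r];
  }
  return true;
}

static double rss_at(const double* s, const double* y, int n,
                     double b, double t, double m, double h) {
  double rss = 0;
  for (int i = 0; i < n; ++i) {
    double r = b + (t - b) * logistic_u(h, m, s[i]) - y[i];
    rss += r * r;
  }
  return rss;
}

// Levenberg-Marquardt refinement of (b, t, m, ln h) from a start point.
// Box constraints keep m near the tested dose window and h in [0.05, 20].
static double lm_refine(const double* s, const double* y, int n,
                        double smin, double smax,
                        double* b, double* t, double* m, double* lnh) {
  double p[4] = {*b, *t, *m, *lnh};
  double lam = 1e-3;
  double rss = rss_at(s, y, n, p[0], p[1], p[2], std::exp(p[3]));
  const double m_lo = smin - 3.0, m_hi = smax + 3.0;
  const double lnh_lo = std::log(0.05), lnh_hi = std::log(20.0);
  for (int iter = 0; iter < 60; ++iter) {
    double h = std::exp(p[3]);
    double JtJ[4][4] = {{0}}, Jtr[4] = {0};
    for (int i = 0; i < n; ++i) {
      double u = logistic_u(h, p[2], s[i]);
      double w = u * (1.0 - u);
      double J[4];
      J[0] = 1.0 - u;                               // d/db
      J[1] = u;                                     // d/dt
      J[2] = -(p[1] - p[0]) * LN10 * h * w;         // d/dm
      J[3] = -(p[1] - p[0]) * LN10 * h * (p[2] - s[i]) * w;  // d/dlnh
      double r = p[0] + (p[1] - p[0]) * u - y[i];
      for (int a = 0; a < 4; ++a) {
        Jtr[a] += J[a] * r;
        for (int c2 = 0; c2 < 4; ++c2) JtJ[a][c2] += J[a] * J[c2];
      }
    }
    bool accepted = false;
    for (int tries = 0; tries < 8; ++tries) {
      double A[4][4], rhs[4], delta[4];
      for (int a = 0; a < 4; ++a) {
        for (int c2 = 0; c2 < 4; ++c2) A[a][c2] = JtJ[a][c2];
        A[a][a] += lam * (JtJ[a][a] > 1e-12 ? JtJ[a][a] : 1e-12);
        rhs[a] = -Jtr[a];
      }
      if (!solve4(A, rhs, delta)) { lam *= 10; continue; }
      double q[4];
      for (int a = 0; a < 4; ++a) q[a] = p[a] + delta[a];
      if (q[2] < m_lo) q[2] = m_lo;
      if (q[2] > m_hi) q[2] = m_hi;
      if (q[3] < lnh_lo) q[3] = lnh_lo;
      if (q[3] > lnh_hi) q[3] = lnh_hi;
      double new_rss = rss_at(s, y, n, q[0], q[1], q[2], std::exp(q[3]));
      if (std::isfinite(new_rss) && new_rss <= rss) {
        bool done = (rss - new_rss) < 1e-12 * (rss + 1e-12);
        for (int a = 0; a < 4; ++a) p[a] = q[a];
        rss = new_rss;
        lam = std::max(lam / 3.0, 1e-12);
        accepted = true;
        if (done) iter = 1000;  // converged
        break;
      }
      lam *= 5.0;
    }
    if (!accepted) break;
  }
  *b = p[0]; *t = p[1]; *m = p[2]; *lnh = p[3];
  return rss;
}

// Full multi-start fit of one dose-response series.
// out: bottom, top, ec50, hill, rss, converged(0/1)
static void fit4pl_one(const double* s, const double* y, int n, double* out) {
  double smin = s[0], smax = s[0], ssum = 0, ysum = 0;
  for (int i = 0; i < n; ++i) {
    smin = std::min(smin, s[i]); smax = std::max(smax, s[i]);
    ssum += s[i]; ysum += y[i];
  }
  double ybar = ysum / n;
  double flat_rss = 0;
  for (int i = 0; i < n; ++i) flat_rss += (y[i] - ybar) * (y[i] - ybar);

  // coarse variable-projection grid: m at each observed dose, h in {0.5,1,2}
  const double hgrid[3] = {0.5, 1.0, 2.0};
  double best_rss = R_PosInf, best_b = ybar, best_t = ybar;
  double best_m = 0.5 * (smin + smax), best_h = 1.0;
  for (int ih = 0; ih < 3; ++ih) {
    for (int im = 0; im < n; ++im) {
      double b, t;
      double rss = varpro_rss(s, y, n, s[im], hgrid[ih], &b, &t);
      if (rss < best_rss) {
        best_rss = rss; best_b = b; best_t = t;
        best_m = s[im]; best_h = hgrid[ih];
      }
    }
  }
  // LM polish from the three best grid h values at the best m, plus the
  // overall best grid point; keep the lowest-RSS refined fit
  double fb = best_b, ft = best_t, fm = best_m, fh = best_h, frss = best_rss;
  bool converged = std::isfinite(best_rss);
  for (int ih = 0; ih < 3; ++ih) {
    double b = best_b, t = best_t, m = best_m, lnh = std::log(hgrid[ih]);
    double rss = lm_refine(s, y, n, smin, smax, &b, &t, &m, &lnh);
    if (std::isfinite(rss) && rss < frss && t >= b) {
      frss = rss; fb = b; ft = t; fm = m; fh = std::exp(lnh);
    }
  }
  {
    double b = best_b, t = best_t, m = best_m, lnh = std::log(best_h);
    double rss = lm_refine(s, y, n, smin, smax, &b, &t, &m, &lnh);
    if (std::isfinite(rss) && rss < frss && t >= b) {
      frss = rss; fb = b; ft = t; fm = m; fh = std::exp(lnh);
    }
  }
  if (!converged || !std::isfinite(frss)) {
    // fallback: flat fit at the mean response
    out[0] = ybar; out[1] = ybar;
    out[2] = std::pow(10.0, 0.5 * (smin + smax)); out[3] = 1.0;
    out[4] = flat_rss; out[5] = 0.0;
    return;
  }
  if (ft - fb < 1e-10) {  // effectively flat: canonical flat representation
    fb = ft = fb + 0.5 * (ft - fb);
    fm = 0.5 * (smin + smax); fh = 1.0;
  }
  out[0] = fb; out[1] = ft; out[2] = std::pow(10.0, fm);
  out[3] = fh; out[4] = frss; out[5] = 1.0;
}

// [[Rcpp::export]]
NumericVector fit4pl_c(NumericVector log10_dose, NumericVector response) {
  int n = log10_dose.size();
  NumericVector out(6);
  fit4pl_one(REAL(log10_dose), REAL(response), n, REAL(out));
  return out;
}

// Batch fitting: series k occupies positions offsets[k] .. offsets[k+1]-1
// (0-based) of the concatenated log10-dose / response vectors.
// [[Rcpp::export]]
NumericMatrix fit4pl_batch_c(NumericVector log10_dose, NumericVector response,
                             IntegerVector offsets) {
  int K = offsets.size() - 1;
  NumericMatrix out(K, 6);
  double buf[6];
  for (int k = 0; k < K; ++k) {
    int a = offsets[k], b = offsets[k + 1];
    fit4pl_one(REAL(log10_dose) + a, REAL(response) + a, b - a, buf);
    for (int c = 0; c < 6; ++c) out(k, c) = buf[c];
    if (k % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
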