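#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Gaussian kernel sum of `x` around query q with bandwidth h, optionally
// excluding index `skip` (-1 for none). Returns the *density*:
//   (1 / (n_eff * h)) * sum phi((q - x_j) / h)
static double kde_at(const double* x, int n, double q, double h, int skip) {
  const double inv_sqrt_2pi = 0.3989422804014326779399461;
  double s = 0.0;
  int n_eff = 0;
  for (int j = 0; j < n; ++j) {
    if (j == skip) continue;
    double z = (q - x[j]) / h;
    s += std::exp(-0.5 * z * z);
    ++n_eff;
  }
  if (n_eff == 0) return 0.0;
  return s * inv_sqrt_2pi / (n_eff * h);
}

// Leave-one-out KDE classification of a single vector.
// values: all samples; is_case: logical per sample; h_case/h_ref: per-class
// bandwidths (computed once on the full class). For sample i the kernel sum
// of its own class omits i. Tie (equal densities) predicts reference.
// [[Rcpp::export]]
LogicalVector loo_kde_predict_c(NumericVector values, LogicalVector is_case,
                                double h_case, double h_ref, bool loo) {
  int n = values.size();
  std::vector<double> xc, xr;
  std::vector<int> idxc, idxr;
  xc.reserve(n); xr.reserve(n);
  for (int i = 0; i < n; ++i) {
    if (is_case[i]) { xc.push_back(values[i]); idxc.push_back(i); }
    else            { xr.push_back(values[i]); idxr.push_back(i); }
  }
  LogicalVector pred(n);
  // position of sample i inside its own class vector (or -1)
  std::vector<int> pos(n, -1);
  for (size_t k = 0; k < idxc.size(); ++k) pos[idxc[k]] = (int)k;
  for (size_t k = 0; k < idxr.size(); ++k) pos[idxr[k]] = (int)k;
  for (int i = 0; i < n; ++i) {
    int skip_c = (loo && is_case[i]) ? pos[i] : -1;
    int skip_r = (loo && !is_case[i]) ? pos[i] : -1;
    double dc = kde_at(xc.data(), (int)xc.size(), values[i], h_case, skip_c);
    double dr = kde_at(xr.data(), (int)xr.size(), values[i], h_ref, skip_r);
    pred[i] = dc > dr;  // tie -> reference (majority class)
  }
  return pred;
}

static double mcc_from_counts(double tp, double tn, double fp, double fn) {
  double d1 = tp + fp, d2 = tp + fn, d3 = tn + fp, d4 = tn + fn;
  if (d1 == 0.0 || d2 == 0.0 || d3 == 0.0 || d4 == 0.0) return 0.0;
  return (tp * tn - fp * fn) / std::sqrt(d1 * d2 * d3 * d4);
}

// Kernel MCC for every row of a genes x samples matrix. Per-gene bandwidths
// are supplied (vectorised Silverman/Scott computed in R). Rows flagged in
// `degenerate` (zero spread in both classes) are assigned 0 directly.
// [[Rcpp::export]]
NumericVector kernel_mcc_rows_c(NumericMatrix mat, LogicalVector is_case,
                                NumericVector h_case, NumericVector h_ref,
                                LogicalVector degenerate) {
  int ng = mat.nrow(), n = mat.ncol();
  std::vector<int> idxc, idxr;
  for (int i = 0; i < n; ++i) (is_case[i] ? idxc : idxr).push_back(i);
  int nc = (int)idxc.size(), nr = (int)idxr.size();
  NumericVector out(ng);
  std::vector<double> xc(nc), xr(nr);
  for (int g = 0; g < ng; ++g) {
    if (degenerate[g]) { out[g] = 0.0; continue; }
    for (int k = 0; k < nc; ++k) xc[k] = mat(g, idxc[k]);
    for (int k = 0; k < nr; ++k) xr[k] = mat(g, idxr[k]);
    double hc = h_case[g], hr = h_ref[g];
    double tp = 0, tn = 0, fp = 0, fn = 0;
    for (int k = 0; k < nc; ++k) {
      double q = xc[k];
      double dc = kde_at(xc.data(), nc, q, hc, k);
      double dr = kde_at(xr.data(), nr, q, hr, -1);
      if (dc > dr) tp += 1; else fn += 1;
    }
    for (int k = 0; k < nr; ++k) {
      double q = xr[k];
      double dc = kde_at(xc.data(), nc, q, hc, -1);
      double dr = kde_at(xr.data(), nr, q, hr, k);
      if (dc > dr) fp += 1; else tn += 1;
    }
    out[g] = mcc_from_counts(tp, tn, fp, fn);
    if (g % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
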