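// O(n^2) template-matching kernels behind the nonlinear-dynamics features.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double cheb(const double* x, int i, int j, int m) {
  double d = 0.0;
  for (int k = 0; k < m; ++k) {
    double a = std::fabs(x[i + k] - x[j + k]);
    if (a > d) d = a;
  }
  return d;
}

// Ordered-pair match counts (i != j, templates 1..n-m) at lengths m and m+1.
// [[Rcpp::export]]
NumericVector sampen_counts_cpp(NumericVector x, int m, double r) {
  int n = x.size();
  int np = n - m;
  const double* p = x.begin();
  double B = 0.0, A = 0.0;
  for (int i = 0; i < np - 1; ++i) {
    for (int j = i + 1; j < np; ++j) {
      double d = cheb(p, i, j, m);
      if (d <= r) {
        B += 1.0;
        double a = std::fabs(p[i + m] - p[j + m]);
        if (a > d) d = a;
        if (d <= r) A += 1.0;
      }
    }
  }
  return NumericVector::create(2.0 * A, 2.0 * B);
}

// Phi_m = mean over templates of log(fraction of templates within r,
// self-match included); templates 1..n-m+1.
// [[Rcpp::export]]
double apen_phi_cpp(NumericVector x, int m, double r) {
  int n = x.size();
  int nt = n - m + 1;
  const double* p = x.begin();
  std::vector<double> cnt(nt, 1.0);  // self-match
  for (int i = 0; i < nt - 1; ++i)
    for (int j = i + 1; j < nt; ++j)
      if (cheb(p, i, j, m) <= r) { cnt[i] += 1.0; cnt[j] += 1.0; }
  double s = 0.0;
  for (int i = 0; i < nt; ++i) s += std::log(cnt[i] / nt);
  return s / nt;
}

// Mean exponential fuzzy similarity exp(-(d^fn)/r) over ordered pairs
// i != j of baseline-removed templates 1..n-m (Chen's fuzzy entropy).
// [[Rcpp::export]]
double fuzzyen_phi_cpp(NumericVector x, int m, double r, double fn) {
  int n = x.size();
  int np = n - m;
  const double* p = x.begin();
  std::vector<double> mu(np);
  for (int i = 0; i < np; ++i) {
    double s = 0.0;
    for (int k = 0; k < m; ++k) s += p[i + k];
    mu[i] = s / m;
  }
  double acc = 0.0;
  for (int i = 0; i < np - 1; ++i) {
    for (int j = i + 1; j < np; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double a = std::fabs((p[i + k] - mu[i]) - (p[j + k] - mu[j]));
        if (a > d) d = a;
      }
      acc += std::exp(-std::pow(d, fn) / r);
    }
  }
  return 2.0 * acc / ((double)np * (np - 1));
}

// Histogram (equal-width bins over [0, max distance]) of all pairwise
// Chebyshev template distances at embedding m; templates 1..n-m+1.
// [[Rcpp::export]]
IntegerVector disten_hist_cpp(NumericVector x, int m, int bins) {
  int n = x.size();
  int nt = n - m + 1;
  const double* p = x.begin();
  long np = (long)nt * (nt - 1) / 2;
  std::vector<double> d;
  d.reserve(np);
  double dmax = 0.0;
  for (int i = 0; i < nt - 1; ++i)
    for (int j = i + 1; j < nt; ++j) {
      double v = cheb(p, i, j, m);
      if (v > dmax) dmax = v;
      d.push_back(v);
    }
  IntegerVector h(bins);
  if (dmax <= 0.0) stop("degenerate (constant) template distances");
  for (size_t k = 0; k < d.size(); ++k) {
    int b = (int)std::floor(d[k] / dmax * bins);
    if (b >= bins) b = bins - 1;
    h[b] += 1;
  }
  return h;
}
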