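#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Triangular membership with feet (l, r) and apex v. The apex is allowed to
// drift inside the epoch while the feet stay where they were derived at the
// start of the epoch, so ordering can degenerate transiently; a collapsed
// triangle responds only at its apex.
static inline double trimf(double x, double l, double v, double r) {
  if (x == v) return 1.0;
  if (x <= l || x >= r || v <= l || v >= r) return 0.0;
  if (x < v) return (x - l) / (v - l);
  return (r - x) / (r - v);
}

struct FunSet {
  // per class: m apexes and weights for one feature
  std::vector<double> v, w, l, r;
};

static void derive_feet(FunSet &fs) {
  const int m = (int)fs.v.size();
  // sort apex/weight pairs by apex
  std::vector<int> idx(m);
  for (int i = 0; i < m; ++i) idx[i] = i;
  std::stable_sort(idx.begin(), idx.end(),
                   [&](int a, int b) { return fs.v[a] < fs.v[b]; });
  std::vector<double> v2(m), w2(m);
  for (int i = 0; i < m; ++i) { v2[i] = fs.v[idx[i]]; w2[i] = fs.w[idx[i]]; }
  fs.v = v2; fs.w = w2;
  fs.l.assign(m, 0.0); fs.r.assign(m, 0.0);
  double span = (m > 1) ? std::max(fs.v[m - 1] - fs.v[0], 1e-6) / (m - 1) : 0.5;
  for (int i = 0; i < m; ++i) {
    double lo = (i > 0) ? fs.v[i - 1] : fs.v[0] - span;
    double hi = (i < m - 1) ? fs.v[i + 1] : fs.v[m - 1] + span;
    if (lo >= fs.v[i]) lo = fs.v[i] - 1e-6;
    if (hi <= fs.v[i]) hi = fs.v[i] + 1e-6;
    fs.l[i] = lo; fs.r[i] = hi;
  }
}

// index of the maximally responding function; all-zero memberships fall back
// to the nearest apex so coverage can recover when apexes have migrated
static inline int winner(const FunSet &fs, double x, double &mu) {
  const int m = (int)fs.v.size();
  int best = 0; double bmu = -1.0;
  for (int i = 0; i < m; ++i) {
    double m_i = trimf(x, fs.l[i], fs.v[i], fs.r[i]);
    if (m_i > bmu) { bmu = m_i; best = i; }
  }
  if (bmu <= 0.0) {
    double bd = R_PosInf;
    for (int i = 0; i < m; ++i) {
      double d = std::abs(x - fs.v[i]);
      if (d < bd) { bd = d; best = i; }
    }
    bmu = 0.0;
  }
  mu = bmu;
  return best;
}

// Online NEWFM update loop. x: n x p matrix scaled to [0,1]; y: 0/1 labels;
// a0/a1, w0/w1: m x p apex and weight matrices for class 0 / class 1.
// Each sample pulls the winning apex of its own class toward the value and
// reinforces its weight; the winning function of the opposite class is
// weakened. Feet are re-derived from sorted neighbouring apexes once per
// epoch.
// [[Rcpp::export]]
List newfm_train_cpp(NumericMatrix x, IntegerVector y,
                     NumericMatrix a0, NumericMatrix a1,
                     NumericMatrix w0, NumericMatrix w1,
                     double alpha, double beta, int epochs) {
  const int n = x.nrow(), p = x.ncol(), m = a0.nrow();
  std::vector<FunSet> f0(p), f1(p);
  for (int j = 0; j < p; ++j) {
    f0[j].v.resize(m); f0[j].w.resize(m);
    f1[j].v.resize(m); f1[j].w.resize(m);
    for (int i = 0; i < m; ++i) {
      f0[j].v[i] = a0(i, j); f0[j].w[i] = w0(i, j);
      f1[j].v[i] = a1(i, j); f1[j].w[i] = w1(i, j);
    }
  }
  for (int e = 0; e < epochs; ++e) {
    for (int j = 0; j < p; ++j) { derive_feet(f0[j]); derive_feet(f1[j]); }
    for (int s = 0; s < n; ++s) {
      const bool cls1 = (y[s] == 1);
      for (int j = 0; j < p; ++j) {
        FunSet &own = cls1 ? f1[j] : f0[j];
        FunSet &oth = cls1 ? f0[j] : f1[j];
        const double xv = x(s, j);
        double mu_own, mu_oth;
        int k = winner(own, xv, mu_own);
        int q = winner(oth, xv, mu_oth);
        own.v[k] += alpha * (xv - own.v[k]);
        own.w[k] = std::min(1.0, own.w[k] + beta * (1.0 - own.w[k]) * mu_own);
        oth.w[q] = std::max(0.0, oth.w[q] - beta * oth.w[q] * mu_oth);
      }
    }
  }
  // canonical (sorted) form for the caller
  for (int j = 0; j < p; ++j) { derive_feet(f0[j]); derive_feet(f1[j]); }
  NumericMatrix A0(m, p), A1(m, p), W0(m, p), W1(m, p);
  for (int j = 0; j < p; ++j)
    for (int i = 0; i < m; ++i) {
      A0(i, j) = f0[j].v[i]; W0(i, j) = f0[j].w[i];
      A1(i, j) = f1[j].v[i]; W1(i, j) = f1[j].w[i];
    }
  return List::create(_["a0"] = A0, _["a1"] = A1,
                      _["w0"] = W0, _["w1"] = W1);
}

// Trimmed-mean momentum for a stack of bursts laid out as an
// nb x ns x 3 array (column-major): for each burst, the mean of the
// consecutive-difference magnitudes after dropping the single largest and
// single smallest.
// [[Rcpp::export]]
NumericVector momentum_batch_cpp(NumericVector arr) {
  IntegerVector dims = arr.attr("dim");
  const int nb = dims[0], ns = dims[1];
  NumericVector out(nb);
  const double *p = arr.begin();
  const R_xlen_t ax = (R_xlen_t)nb * ns;
  for (int b = 0; b < nb; ++b) {
    double sum = 0, mx = R_NegInf, mn = R_PosInf;
    for (int s = 1; s < ns; ++s) {
      const R_xlen_t i1 = b + (R_xlen_t)s * nb, i0 = i1 - nb;
      const double dx = p[i1] - p[i0];
      const double dy = p[i1 + ax] - p[i0 + ax];
      const double dz = p[i1 + 2 * ax] - p[i0 + 2 * ax];
      const double m = std::sqrt(dx * dx + dy * dy + dz * dz);
      sum += m;
      if (m > mx) mx = m;
      if (m < mn) mn = m;
    }
    out[b] = (sum - mx - mn) / (ns - 3);
  }
  return out;
}
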