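#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

// DTW distance, dtaidistance convention: squared local cost accumulated over
// monotone paths with steps {(1,0),(0,1),(1,1)}, boundary-anchored, sqrt at
// the end. window <= 0 disables the Sakoe-Chiba band. `prev`/`cur` are
// caller-provided workspaces of length >= m + 1.
static double dtw_dist_core(const double* a, int n, const double* b, int m,
                            int window, double* prev, double* cur) {
  const double inf = std::numeric_limits<double>::infinity();
  int w = window;
  if (w > 0 && w < std::abs(n - m)) w = std::abs(n - m);
  for (int j = 0; j <= m; ++j) prev[j] = inf;
  prev[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    int jlo = 1, jhi = m;
    if (w > 0) {
      jlo = std::max(1, i - w);
      jhi = std::min(m, i + w);
    }
    cur[0] = inf;
    for (int j = jlo - 1; j >= 0; --j) cur[j] = inf;
    if (jhi < m) for (int j = jhi; j <= m; ++j) cur[j] = inf;
    const double ai = a[i - 1];
    for (int j = jlo; j <= jhi; ++j) {
      double d = ai - b[j - 1];
      d *= d;
      double best = prev[j - 1];
      if (prev[j] < best) best = prev[j];
      if (cur[j - 1] < best) best = cur[j - 1];
      cur[j] = d + best;
    }
    std::swap(prev, cur);
  }
  return std::sqrt(prev[m]);
}

// [[Rcpp::export]]
double dtw_dist_cpp(NumericVector a, NumericVector b, int window) {
  std::vector<double> prev(b.size() + 1), cur(b.size() + 1);
  return dtw_dist_core(a.begin(), a.size(), b.begin(), b.size(), window,
                       prev.data(), cur.data());
}

// [[Rcpp::export]]
NumericMatrix pairwise_dtw_cpp(List A, List B, int window, bool symmetric) {
  int na = A.size(), nb = B.size();
  std::vector<NumericVector> av(na), bv(nb);
  int mmax = 1;
  for (int i = 0; i < na; ++i) {
    av[i] = as<NumericVector>(A[i]);
    mmax = std::max(mmax, (int) av[i].size());
  }
  for (int j = 0; j < nb; ++j) {
    bv[j] = as<NumericVector>(B[j]);
    mmax = std::max(mmax, (int) bv[j].size());
  }
  std::vector<double> prev(mmax + 1), cur(mmax + 1);
  NumericMatrix D(na, nb);
  if (symmetric) {
    for (int i = 0; i < na; ++i) {
      const double* ai = av[i].begin();
      int ni = av[i].size();
      for (int j = i + 1; j < nb; ++j) {
        double d = dtw_dist_core(ai, ni, bv[j].begin(), bv[j].size(),
                                 window, prev.data(), cur.data());
        D(i, j) = d;
        D(j, i) = d;
      }
    }
  } else {
    for (int i = 0; i < na; ++i) {
      const double* ai = av[i].begin();
      int ni = av[i].size();
      for (int j = 0; j < nb; ++j) {
        D(i, j) = dtw_dist_core(ai, ni, bv[j].begin(), bv[j].size(),
                                window, prev.data(), cur.data());
      }
    }
  }
  return D;
}
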