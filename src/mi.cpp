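#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

// Deterministic uniform stream (splitmix-style LCG) used to break ties before
// neighbour search; the KSG derivation assumes continuous marginals and
// expression matrices contain exact ties. The same stream is added to both
// coordinates so that the estimate is exactly symmetric in (x, y) and
// invariant under feature relabelling.
static std::vector<double> jitter_stream(int n, uint64_t seed) {
  std::vector<double> u(n);
  uint64_t s = seed * 2862933555777941757ULL + 3037000493ULL;
  for (int i = 0; i < n; ++i) {
    s = s * 6364136223846793005ULL + 1442695040888963407ULL;
    u[i] = (double)(s >> 11) * (1.0 / 9007199254740992.0);
  }
  return u;
}

// Kraskov-Stoegbauer-Grassberger estimator, algorithm 1: Chebyshev (max) norm
// in the joint space, eps_i = distance to the k-th nearest neighbour,
// marginal counts strictly inside eps_i, digamma corrections, natural log.
static double ksg1(const std::vector<double>& x, const std::vector<double>& y,
                   int k) {
  const int n = (int)x.size();
  std::vector<double> dj(n - 1);
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    int m = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = std::fabs(x[i] - x[j]);
      double dy = std::fabs(y[i] - y[j]);
      dj[m++] = dx > dy ? dx : dy;
    }
    std::nth_element(dj.begin(), dj.begin() + (k - 1), dj.begin() + m);
    const double eps = dj[k - 1];
    int nx = 0, ny = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      if (std::fabs(x[i] - x[j]) < eps) ++nx;
      if (std::fabs(y[i] - y[j]) < eps) ++ny;
    }
    acc += R::digamma(nx + 1.0) + R::digamma(ny + 1.0);
  }
  double mi = R::digamma((double)k) + R::digamma((double)n) - acc / n;
  return mi > 0.0 ? mi : 0.0;
}

// [[Rcpp::export]]
double ksg_mi_cpp(NumericVector x, NumericVector y, int k, double amp,
                  int seed) {
  const int n = x.size();
  std::vector<double> xv(n), yv(n);
  std::vector<double> u = jitter_stream(n, (uint64_t)(uint32_t)seed);
  for (int i = 0; i < n; ++i) {
    xv[i] = x[i] + amp * u[i];
    yv[i] = y[i] + amp * u[i];
  }
  return ksg1(xv, yv, k);
}

// All unordered pairs of rows of `mat` (features x samples); diagonal NA.
// [[Rcpp::export]]
NumericMatrix ksg_mi_matrix_cpp(NumericMatrix mat, int k, double amp,
                                int seed) {
  const int p = mat.nrow(), n = mat.ncol();
  std::vector<double> u = jitter_stream(n, (uint64_t)(uint32_t)seed);
  std::vector< std::vector<double> > rows(p, std::vector<double>(n));
  for (int i = 0; i < p; ++i)
    for (int s = 0; s < n; ++s)
      rows[i][s] = mat(i, s) + amp * u[s];
  NumericMatrix out(p, p);
  out.fill(NA_REAL);
  for (int i = 0; i < p - 1; ++i) {
    for (int j = i + 1; j < p; ++j) {
      double mi = ksg1(rows[i], rows[j], k);
      out(i, j) = mi;
      out(j, i) = mi;
    }
  }
  return out;
}

// ARACNE-style DPI: every unordered triple is evaluated against the original
// matrix and all dominated edges are removed simultaneously. Returns the
// logical keep-mask over edges (i, j).
// [[Rcpp::export]]
LogicalMatrix dpi_keep_cpp(NumericMatrix mi, double eps) {
  const int p = mi.nrow();
  LogicalMatrix keep(p, p);
  keep.fill(true);
  for (int i = 0; i < p - 2; ++i) {
    for (int j = i + 1; j < p - 1; ++j) {
      const double a = mi(i, j);
      for (int k = j + 1; k < p; ++k) {
        const double b = mi(j, k);
        const double c = mi(i, k);
        if (a < b - eps && a < c - eps) { keep(i, j) = false; keep(j, i) = false; }
        if (b < a - eps && b < c - eps) { keep(j, k) = false; keep(k, j) = false; }
        if (c < a - eps && c < b - eps) { keep(i, k) = false; keep(k, i) = false; }
      }
    }
  }
  return keep;
}
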