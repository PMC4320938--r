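#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Dynamic time warping with squared pointwise cost, step set
// {(1,1),(1,0),(0,1)}, boundary-anchored, no band constraint.
// Two-row DP; cost matrix is never materialised.
// [[Rcpp::export]]
double cpp_dtw(NumericVector a, NumericVector b) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("dtw: empty input");
  std::vector<double> prev(m), cur(m);
  for (int j = 0; j < m; ++j) {
    double d = a[0] - b[j];
    prev[j] = d * d + (j > 0 ? prev[j - 1] : 0.0);
  }
  for (int i = 1; i < n; ++i) {
    double d0 = a[i] - b[0];
    cur[0] = d0 * d0 + prev[0];
    for (int j = 1; j < m; ++j) {
      double d = a[i] - b[j];
      double best = prev[j - 1];
      if (prev[j] < best) best = prev[j];
      if (cur[j - 1] < best) best = cur[j - 1];
      cur[j] = d * d + best;
    }
    std::swap(prev, cur);
  }
  return prev[m - 1];
}

static inline void window_stats(const double *cs, const double *css, int i,
                                int m, double &mu, double &sd) {
  double s = cs[i + m] - cs[i];
  double ss = css[i + m] - css[i];
  mu = s / m;
  double v = ss / m - mu * mu;
  sd = v > 0 ? std::sqrt(v) : 0.0;
}

// Exact squared z-normalised Euclidean distance between windows starting at
// i and j (population sd; constant windows map to the all-zero vector).
static double exact_zdist2(const NumericVector &x, int i, int j, int m,
                           const double *cs, const double *css) {
  double mui, sdi, muj, sdj;
  window_stats(cs, css, i, m, mui, sdi);
  window_stats(cs, css, j, m, muj, sdj);
  const double eps = 1e-12;
  double acc = 0.0;
  for (int t = 0; t < m; ++t) {
    double zi = sdi > eps ? (x[i + t] - mui) / sdi : 0.0;
    double zj = sdj > eps ? (x[j + t] - muj) / sdj : 0.0;
    double d = zi - zj;
    acc += d * d;
  }
  return acc;
}

// Closest non-overlapping pair of z-normalised subsequences of length m in a
// raw lead, by sliding dot products along diagonals (O(n^2) independent of
// m).  d^2 = 2m(1 - corr), so the scan maximises the windowed correlation
// with a division-free update; a second pass recomputes all near-maximal
// pairs exactly and ties break to the lexicographically smallest (i, j).
// [[Rcpp::export]]
List cpp_pair_search(NumericVector x, int m) {
  const int n = x.size();
  const int k = n - m + 1;
  if (m < 2) stop("subsequence length must be >= 2");
  if (k < 1) stop("lead shorter than subsequence length");
  std::vector<double> cs(n + 1, 0.0), css(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    cs[i + 1] = cs[i] + x[i];
    css[i + 1] = css[i] + x[i] * x[i];
  }
  std::vector<double> mmu(k), inv(k);
  std::vector<char> cst(k);
  const double eps = 1e-12;
  const double sqm = std::sqrt((double)m);
  for (int i = 0; i < k; ++i) {
    double mu, sd;
    window_stats(cs.data(), css.data(), i, m, mu, sd);
    cst[i] = sd <= eps;
    mmu[i] = m * mu;
    inv[i] = cst[i] ? 0.0 : 1.0 / (sqm * sd);
  }
  const double *xp = REAL(x);
  if (k <= m) stop("no non-overlapping subsequence pair exists");
  // pass 1: approximate maximal correlation (constant windows: corr
  // equivalents are 1 for const/const pairs, 0.5 for const/non-const)
  double best_c = -std::numeric_limits<double>::infinity();
  for (int lag = m; lag < k; ++lag) {
    double qt = 0.0;
    for (int t = 0; t < m; ++t) qt += xp[t] * xp[t + lag];
    for (int i = 0; i + lag < k; ++i) {
      int j = i + lag;
      if (i > 0) qt += xp[i + m - 1] * xp[j + m - 1] - xp[i - 1] * xp[j - 1];
      double c;
      if (cst[i] | cst[j]) {
        c = (cst[i] && cst[j]) ? 1.0 : 0.5;
      } else {
        c = (qt - mmu[i] * (mmu[j] / m)) * inv[i] * inv[j];
      }
      if (c > best_c) best_c = c;
    }
  }
  if (!std::isfinite(best_c)) stop("no non-overlapping subsequence pair exists");
  // pass 2: exact evaluation of near-maximal pairs
  const double tol = 1e-7 * (std::fabs(best_c) + 1.0);
  double best = std::numeric_limits<double>::infinity();
  int bi = -1, bj = -1;
  for (int lag = m; lag < k; ++lag) {
    double qt = 0.0;
    for (int t = 0; t < m; ++t) qt += xp[t] * xp[t + lag];
    for (int i = 0; i + lag < k; ++i) {
      int j = i + lag;
      if (i > 0) qt += xp[i + m - 1] * xp[j + m - 1] - xp[i - 1] * xp[j - 1];
      double c;
      if (cst[i] | cst[j]) {
        c = (cst[i] && cst[j]) ? 1.0 : 0.5;
      } else {
        c = (qt - mmu[i] * (mmu[j] / m)) * inv[i] * inv[j];
      }
      if (c >= best_c - tol) {
        double ex = exact_zdist2(x, i, j, m, cs.data(), css.data());
        if (ex < best || (ex == best && (i < bi || (i == bi && j < bj)))) {
          best = ex;
          bi = i;
          bj = j;
        }
      }
    }
  }
  if (bi < 0) stop("no non-overlapping subsequence pair exists");
  return List::create(_["i"] = bi, _["j"] = bj, _["dist2"] = best);
}

// Brute-force closest non-overlapping pair over a matrix of (already
// z-normalised) subsequences (rows), with early abandoning.  Used for the
// public find_motif_candidate() surface on in-memory subsequence sets.
// [[Rcpp::export]]
List cpp_brute_pair(NumericMatrix z, IntegerVector starts, int m) {
  const int k = z.nrow(), len = z.ncol();
  double best = std::numeric_limits<double>::infinity();
  int bi = -1, bj = -1;
  for (int i = 0; i < k; ++i) {
    for (int j = i + 1; j < k; ++j) {
      if (std::abs(starts[i] - starts[j]) < m) continue;
      double acc = 0.0;
      for (int t = 0; t < len; ++t) {
        double d = z(i, t) - z(j, t);
        acc += d * d;
        if (acc > best) break;
      }
      if (acc < best) {
        best = acc;
        bi = i;
        bj = j;
      }
    }
  }
  if (bi < 0) stop("no non-overlapping subsequence pair exists");
  return List::create(_["i"] = bi, _["j"] = bj, _["dist2"] = best);
}

// Squared z-normalised distance from every window of x to a fixed
// (z-normalised) centre vector.
// [[Rcpp::export]]
NumericVector cpp_dists_to_center(NumericVector x, int m, NumericVector center) {
  const int n = x.size();
  const int k = n - m + 1;
  if (center.size() != m) stop("center length mismatch");
  std::vector<double> cs(n + 1, 0.0), css(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    cs[i + 1] = cs[i] + x[i];
    css[i + 1] = css[i] + x[i] * x[i];
  }
  const double eps = 1e-12;
  NumericVector out(k);
  for (int i = 0; i < k; ++i) {
    double mu, sd;
    window_stats(cs.data(), css.data(), i, m, mu, sd);
    double acc = 0.0;
    if (sd <= eps) {
      for (int t = 0; t < m; ++t) acc += center[t] * center[t];
    } else {
      for (int t = 0; t < m; ++t) {
        double d = (x[i + t] - mu) / sd - center[t];
        acc += d * d;
      }
    }
    out[i] = acc;
  }
  return out;
}
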