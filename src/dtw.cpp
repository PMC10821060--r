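#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdlib>

using namespace Rcpp;

// Banded multivariate dynamic time warping.
//
// Local cost c(i,j) is the Euclidean distance between row i of `test` and
// row j of `ref` across all channels.  The DP uses the classic step set
// {(1,1),(1,0),(0,1)} under a Sakoe-Chiba band |i-j| <= w (1-based indices).
// Ties in the DP minimum are broken deterministically: the diagonal step is
// preferred, then the test-advancing step (i-1,j), then (i,j-1).
//
// The projected distance anchors the alignment on the test trial: reference
// rows matched to each test index are averaged and the mean per-test-sample
// Euclidean distance is returned, so distances are comparable across trials
// of different lengths.
// [[Rcpp::export(name = ".dtw_band_cpp")]]
List dtw_band_cpp(const NumericMatrix& test, const NumericMatrix& ref,
                  const int w, const bool return_path) {
  const int n = test.nrow();
  const int m = ref.nrow();
  const int C = test.ncol();
  if (ref.ncol() != C)
    stop("test and reference must share the channel set");
  if (n < 1 || m < 1)
    stop("empty sequence");
  if (w < 0)
    stop("window must be nonnegative");
  if (std::abs(n - m) > w) {
    // no monotone path from (1,1) to (n,m) stays inside the band
    return List::create(_["feasible"] = false);
  }

  const double INF = R_PosInf;
  std::vector<double> D((size_t)n * m, INF);
  std::vector<signed char> bp((size_t)n * m, -1);

  const double* tp = REAL(test);
  const double* rp = REAL(ref);

  // row-major copies: sample rows become contiguous for the inner loop
  std::vector<double> trow((size_t)n * C), rrow((size_t)m * C);
  for (int k = 0; k < C; ++k) {
    for (int i = 0; i < n; ++i) trow[(size_t)i * C + k] = tp[i + (size_t)k * n];
    for (int j = 0; j < m; ++j) rrow[(size_t)j * C + k] = rp[j + (size_t)k * m];
  }

  for (int i = 0; i < n; ++i) {
    const int jlo = std::max(0, i - w);
    const int jhi = std::min(m - 1, i + w);
    const double* ti = &trow[(size_t)i * C];
    for (int j = jlo; j <= jhi; ++j) {
      const double* rj = &rrow[(size_t)j * C];
      double s = 0.0;
      for (int k = 0; k < C; ++k) {
        const double d = ti[k] - rj[k];
        s += d * d;
      }
      const double cost = std::sqrt(s);
      const size_t idx = (size_t)i * m + j;
      if (i == 0 && j == 0) {
        D[idx] = cost;
        bp[idx] = -1;
        continue;
      }
      double best = INF;
      signed char b = -1;
      if (i > 0 && j > 0) {               // diagonal, preferred on ties
        best = D[(size_t)(i - 1) * m + (j - 1)];
        b = 0;
      }
      if (i > 0) {                        // test-advancing step
        const double v = D[(size_t)(i - 1) * m + j];
        if (v < best) { best = v; b = 1; }
      }
      if (j > 0) {                        // reference-advancing step
        const double v = D[(size_t)i * m + (j - 1)];
        if (v < best) { best = v; b = 2; }
      }
      D[idx] = cost + best;
      bp[idx] = b;
    }
  }

  const double raw_cost = D[(size_t)(n - 1) * m + (m - 1)];

  // backtrack; accumulate matched reference rows per test index
  std::vector<double> acc((size_t)n * C, 0.0);
  std::vector<int> cnt(n, 0);
  std::vector<int> pi, pj;
  pi.reserve(n + m);
  pj.reserve(n + m);
  int i = n - 1, j = m - 1;
  for (;;) {
    pi.push_back(i + 1);
    pj.push_back(j + 1);
    cnt[i] += 1;
    for (int k = 0; k < C; ++k)
      acc[(size_t)i * C + k] += rrow[(size_t)j * C + k];
    const signed char b = bp[(size_t)i * m + j];
    if (b < 0) break;
    if (b == 0) { --i; --j; }
    else if (b == 1) { --i; }
    else { --j; }
  }

  double pd = 0.0;
  for (int ii = 0; ii < n; ++ii) {
    double s = 0.0;
    for (int k = 0; k < C; ++k) {
      const double rbar = acc[(size_t)ii * C + k] / cnt[ii];
      const double d = trow[(size_t)ii * C + k] - rbar;
      s += d * d;
    }
    pd += std::sqrt(s);
  }
  pd /= n;

  if (!return_path) {
    return List::create(_["feasible"] = true,
                        _["raw_cost"] = raw_cost,
                        _["projected_distance"] = pd);
  }

  const int L = (int)pi.size();
  IntegerMatrix path(L, 2);
  for (int k = 0; k < L; ++k) {          // reverse into forward order
    path(k, 0) = pi[L - 1 - k];
    path(k, 1) = pj[L - 1 - k];
  }
  return List::create(_["feasible"] = true,
                      _["raw_cost"] = raw_cost,
                      _["projected_distance"] = pd,
                      _["path"] = path);
}
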