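// Dynamic time warping with the mixed index/amplitude local cost
//   d(i, j) = sqrt((i - j)^2 + (a_i - b_j)^2)   (i, j 1-based)
// monotone steps {(1,0), (0,1), (1,1)}, endpoints anchored at (1,1) and
// (m,m). Optional Sakoe-Chiba band (|i - j| <= radius) stored as an
// m x (2r+1) strip so stitched multi-minute signals stay tractable.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// [[Rcpp::export]]
List dtw_cpp(NumericVector a, NumericVector b, int radius,
             bool index_cost, bool return_path) {
  const R_xlen_t m = a.size(), n = b.size();
  if (m == 0 || n == 0) stop("empty input to DTW");
  if (radius < 0) radius = (int)std::max(m, n); // full matrix
  const long r = radius;
  if (std::llabs((long long)(m - n)) > r)
    stop("band radius %d cannot connect endpoints of lengths %d and %d",
         radius, (int)m, (int)n);
  const long W = 2 * r + 1;
  if ((double)m * (double)W * 9.0 > 4e9)
    stop("DTW band too large (%g cells); reduce the band radius",
         (double)m * (double)W);

  std::vector<double> cost((size_t)m * W,
                           std::numeric_limits<double>::infinity());
  std::vector<uint8_t> step((size_t)m * W, 255); // 0 diag, 1 up, 2 left
  // column j maps to band slot j - (i - r)
  auto slot = [&](long i, long j) { return (size_t)i * W + (j - (i - r)); };
  auto in_band = [&](long i, long j) {
    return j >= 0 && j < n && j >= i - r && j <= i + r;
  };
  auto local = [&](long i, long j) {
    const double da = a[i] - b[j];
    if (!index_cost) return std::sqrt(da * da);
    const double di = (double)(i - j);
    return std::sqrt(di * di + da * da);
  };

  for (long i = 0; i < m; ++i) {
    const long jlo = std::max(0L, i - r), jhi = std::min((long)n - 1, i + r);
    for (long j = jlo; j <= jhi; ++j) {
      const double d = local(i, j);
      if (i == 0 && j == 0) {
        cost[slot(0, 0)] = d;
        step[slot(0, 0)] = 255;
        continue;
      }
      double best = std::numeric_limits<double>::infinity();
      uint8_t bs = 255;
      if (i > 0 && in_band(i - 1, j - 1) && j > 0) {
        const double c = cost[slot(i - 1, j - 1)];
        if (c < best) { best = c; bs = 0; }
      }
      if (i > 0 && in_band(i - 1, j)) {
        const double c = cost[slot(i - 1, j)];
        if (c < best) { best = c; bs = 1; }
      }
      if (j > 0 && in_band(i, j - 1)) {
        const double c = cost[slot(i, j - 1)];
        if (c < best) { best = c; bs = 2; }
      }
      if (bs != 255) {
        cost[slot(i, j)] = best + d;
        step[slot(i, j)] = bs;
      }
    }
  }

  const double dist = cost[slot(m - 1, n - 1)];
  if (!std::isfinite(dist)) stop("DTW failed to reach the end point");
  if (!return_path)
    return List::create(_["distance"] = dist);

  std::vector<int> pi, pj;
  long i = m - 1, j = n - 1;
  while (true) {
    pi.push_back((int)i + 1);
    pj.push_back((int)j + 1);
    const uint8_t s = step[slot(i, j)];
    if (s == 255) break;
    if (s == 0) { --i; --j; }
    else if (s == 1) { --i; }
    else { --j; }
  }
  std::reverse(pi.begin(), pi.end());
  std::reverse(pj.begin(), pj.end());
  return List::create(_["distance"] = dist,
                      _["path_i"] = IntegerVector(pi.begin(), pi.end()),
                      _["path_j"] = IntegerVector(pj.begin(), pj.end()));
}
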