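#include <Rcpp.h>
#include <vector>
#include <deque>
#include <cmath>
using namespace Rcpp;

// Connected-component labelling of a binary 3D mask (26-connectivity).
// Returns integer labels, 0 outside the mask, components numbered from 1.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n);
  int next = 0;
  std::deque<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    lab[s] = next;
    q.push_back(s);
    while (!q.empty()) {
      R_xlen_t k = q.front(); q.pop_front();
      int x = (int)(k % nx), y = (int)((k / nx) % ny), z = (int)(k / ((R_xlen_t)nx * ny));
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
            R_xlen_t kk = (R_xlen_t)xx + (R_xlen_t)nx * ((R_xlen_t)yy + (R_xlen_t)ny * zz);
            if (mask[kk] && !lab[kk]) { lab[kk] = next; q.push_back(kk); }
          }
    }
  }
  return lab;
}

// For each row of A (n x 3), the distance to its nearest row of B (m x 3).
// [[Rcpp::export]]
NumericVector nearest_dist_cpp(NumericMatrix A, NumericMatrix B) {
  const int n = A.nrow(), m = B.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    for (int j = 0; j < m; ++j) {
      double dx = ax - B(j, 0), dy = ay - B(j, 1), dz = az - B(j, 2);
      double d = dx * dx + dy * dy + dz * dz;
      if (d < best) best = d;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Farthest-point subsampling: greedily pick k points maximizing the minimum
// distance to those already chosen, starting from `start` (0-based).
// Returns 0-based indices in pick order.
// [[Rcpp::export]]
IntegerVector farthest_point_sample_cpp(NumericMatrix P, int k, int start) {
  const int n = P.nrow();
  IntegerVector out(k);
  std::vector<double> mind(n, R_PosInf);
  int cur = start;
  for (int t = 0; t < k; ++t) {
    out[t] = cur;
    double cx = P(cur, 0), cy = P(cur, 1), cz = P(cur, 2);
    int nxt = 0;
    double best = -1.0;
    for (int i = 0; i < n; ++i) {
      double dx = cx - P(i, 0), dy = cy - P(i, 1), dz = cz - P(i, 2);
      double d = dx * dx + dy * dy + dz * dz;
      if (d < mind[i]) mind[i] = d;
      if (mind[i] > best) { best = mind[i]; nxt = i; }
    }
    cur = nxt;
  }
  return out;
}
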