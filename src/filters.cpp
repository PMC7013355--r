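#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Index helpers: volumes are R arrays (column-major), dims = (nx, ny, nz).
static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}
static inline R_xlen_t lin(int x, int y, int z, int nx, int ny) {
  return (R_xlen_t)x + (R_xlen_t)nx * ((R_xlen_t)y + (R_xlen_t)ny * (R_xlen_t)z);
}

// Local mean and variance over a cubic window (edge replication at borders),
// via summed-volume tables so the cost is independent of window size.
// Returns a list with mean and variance arrays.
// [[Rcpp::export]]
List local_mean_var_cpp(NumericVector vol, IntegerVector dims, int window) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int h = window / 2;
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;

  // padded integral volumes of x and x^2 with replicated borders
  const int px = nx + 2 * h, py = ny + 2 * h, pz = nz + 2 * h;
  std::vector<double> s1((R_xlen_t)(px + 1) * (py + 1) * (pz + 1), 0.0);
  std::vector<double> s2(s1.size(), 0.0);
  const R_xlen_t sx = 1, sy = px + 1, sz = (R_xlen_t)(px + 1) * (py + 1);
  for (int z = 0; z < pz; ++z) {
    for (int y = 0; y < py; ++y) {
      for (int x = 0; x < px; ++x) {
        double v = vol[lin(clampi(x - h, 0, nx - 1), clampi(y - h, 0, ny - 1),
                           clampi(z - h, 0, nz - 1), nx, ny)];
        R_xlen_t i = (x + 1) * sx + (R_xlen_t)(y + 1) * sy + (R_xlen_t)(z + 1) * sz;
        s1[i] = v + s1[i - sx] + s1[i - sy] + s1[i - sz]
              - s1[i - sx - sy] - s1[i - sx - sz] - s1[i - sy - sz]
              + s1[i - sx - sy - sz];
        s2[i] = v * v + s2[i - sx] + s2[i - sy] + s2[i - sz]
              - s2[i - sx - sy] - s2[i - sx - sz] - s2[i - sy - sz]
              + s2[i - sx - sy - sz];
      }
    }
  }
  NumericVector mean_(n), var_(n);
  const double cnt = (double)window * window * window;
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        // window in padded coords: [x, x+window) etc. (center x+h in padded)
        R_xlen_t a = (R_xlen_t)x * sx + (R_xlen_t)y * sy + (R_xlen_t)z * sz;
        R_xlen_t b = (R_xlen_t)(x + window) * sx + (R_xlen_t)(y + window) * sy +
                     (R_xlen_t)(z + window) * sz;
        auto boxsum = [&](std::vector<double> &s) {
          return s[b]
               - s[b - (R_xlen_t)window * sx] - s[b - (R_xlen_t)window * sy]
               - s[b - (R_xlen_t)window * sz]
               + s[a + (R_xlen_t)window * sz] + s[a + (R_xlen_t)window * sy]
               + s[a + (R_xlen_t)window * sx] - s[a];
        };
        double m = boxsum(s1) / cnt;
        double q = boxsum(s2) / cnt - m * m;
        R_xlen_t i = lin(x, y, z, nx, ny);
        mean_[i] = m;
        var_[i] = q > 0 ? q : 0.0;
      }
    }
  }
  return List::create(_["mean"] = mean_, _["var"] = var_);
}

// Local order statistics over a cubic window: median, and the normalized rank
// of the center voxel (fraction of the other window voxels it exceeds, ties
// counted half). Border handled by edge replication.
// [[Rcpp::export]]
List local_rank_median_cpp(NumericVector vol, IntegerVector dims, int window) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int h = window / 2;
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const int wn = window * window * window;
  NumericVector rank_(n), med_(n);
  std::vector<double> buf(wn);
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        double c = vol[lin(x, y, z, nx, ny)];
        int k = 0, below = 0, ties = 0;
        for (int dz = -h; dz <= h; ++dz)
          for (int dy = -h; dy <= h; ++dy)
            for (int dx = -h; dx <= h; ++dx) {
              double v = vol[lin(clampi(x + dx, 0, nx - 1), clampi(y + dy, 0, ny - 1),
                                 clampi(z + dz, 0, nz - 1), nx, ny)];
              buf[k++] = v;
              if (v < c) ++below; else if (v == c) ++ties;
            }
        // center itself is among the ties; exclude it from the comparison set
        rank_[lin(x, y, z, nx, ny)] = (below + 0.5 * (ties - 1)) / (double)(wn - 1);
        std::nth_element(buf.begin(), buf.begin() + wn / 2, buf.end());
        med_[lin(x, y, z, nx, ny)] = buf[wn / 2];
      }
    }
  }
  return List::create(_["rank"] = rank_, _["median"] = med_);
}

// Local histogram entropy (bits) of intensities quantized to nbins over the
// global min..max range. A constant volume yields zero everywhere.
// [[Rcpp::export]]
NumericVector local_entropy_cpp(NumericVector vol, IntegerVector dims, int window,
                                int nbins) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int h = window / 2;
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  double lo = R_PosInf, hi = R_NegInf;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (vol[i] < lo) lo = vol[i];
    if (vol[i] > hi) hi = vol[i];
  }
  std::vector<int> q(n);
  if (hi > lo) {
    double scale = nbins / (hi - lo);
    for (R_xlen_t i = 0; i < n; ++i) {
      int b = (int)((vol[i] - lo) * scale);
      q[i] = b >= nbins ? nbins - 1 : b;
    }
  } // else all zero
  NumericVector ent(n);
  std::vector<int> histo(nbins);
  const double wn = (double)window * window * window;
  const double log2e = 1.0 / std::log(2.0);
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        std::fill(histo.begin(), histo.end(), 0);
        for (int dz = -h; dz <= h; ++dz)
          for (int dy = -h; dy <= h; ++dy)
            for (int dx = -h; dx <= h; ++dx)
              ++histo[q[lin(clampi(x + dx, 0, nx - 1), clampi(y + dy, 0, ny - 1),
                            clampi(z + dz, 0, nz - 1), nx, ny)]];
        double H = 0.0;
        for (int b = 0; b < nbins; ++b)
          if (histo[b] > 0) {
            double p = histo[b] / wn;
            H -= p * std::log(p) * log2e;
          }
        ent[lin(x, y, z, nx, ny)] = H;
      }
    }
  }
  return ent;
}

// 6-neighbor discrete Laplacian (edge replication).
// [[Rcpp::export]]
NumericVector laplacian6_cpp(NumericVector vol, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        double c = vol[lin(x, y, z, nx, ny)];
        double s = vol[lin(clampi(x - 1, 0, nx - 1), y, z, nx, ny)]
                 + vol[lin(clampi(x + 1, 0, nx - 1), y, z, nx, ny)]
                 + vol[lin(x, clampi(y - 1, 0, ny - 1), z, nx, ny)]
                 + vol[lin(x, clampi(y + 1, 0, ny - 1), z, nx, ny)]
                 + vol[lin(x, y, clampi(z - 1, 0, nz - 1), nx, ny)]
                 + vol[lin(x, y, clampi(z + 1, 0, nz - 1), nx, ny)];
        out[lin(x, y, z, nx, ny)] = s - 6.0 * c;
      }
  return out;
}
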