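#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <deque>
using namespace Rcpp;

// Slice-wise Canny edge detector. The volume is cut into 2D slices along
// `axis` (0-based); each slice gets Sobel gradients, non-maximum suppression
// over four quantized directions, and hysteresis thresholding at fixed
// fractions (low, high) of that slice's gradient-magnitude maximum.
// Output is a binary 0/1 volume.
// [[Rcpp::export]]
NumericVector canny_slices_cpp(NumericVector vol, IntegerVector dims, int axis,
                               double low_frac, double high_frac) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out((R_xlen_t)nx * ny * nz);

  // slice dimensions (u, v) and the slice axis s
  int du, dv;
  if (axis == 0) { du = 1; dv = 2; }
  else if (axis == 1) { du = 0; dv = 2; }
  else { du = 0; dv = 1; }
  const int dimv[3] = {nx, ny, nz};
  const int nu = dimv[du], nv = dimv[dv], ns = dimv[axis];

  auto volAt = [&](int s, int u, int v) -> double {
    int c[3]; c[axis] = s; c[du] = u; c[dv] = v;
    return vol[(R_xlen_t)c[0] + (R_xlen_t)nx * ((R_xlen_t)c[1] + (R_xlen_t)ny * c[2])];
  };
  auto outIdx = [&](int s, int u, int v) -> R_xlen_t {
    int c[3]; c[axis] = s; c[du] = u; c[dv] = v;
    return (R_xlen_t)c[0] + (R_xlen_t)nx * ((R_xlen_t)c[1] + (R_xlen_t)ny * c[2]);
  };
  auto cl = [](int x, int hi) { return x < 0 ? 0 : (x > hi ? hi : x); };

  std::vector<double> mag((R_xlen_t)nu * nv), gu(mag.size()), gv(mag.size());
  std::vector<unsigned char> keep(mag.size()), strong(mag.size());

  for (int s = 0; s < ns; ++s) {
    double mmax = 0.0;
    for (int v = 0; v < nv; ++v)
      for (int u = 0; u < nu; ++u) {
        // Sobel with replicated borders
        double p[3][3];
        for (int j = -1; j <= 1; ++j)
          for (int i = -1; i <= 1; ++i)
            p[j + 1][i + 1] = volAt(s, cl(u + i, nu - 1), cl(v + j, nv - 1));
        double gx = (p[0][2] + 2 * p[1][2] + p[2][2]) - (p[0][0] + 2 * p[1][0] + p[2][0]);
        double gy = (p[2][0] + 2 * p[2][1] + p[2][2]) - (p[0][0] + 2 * p[0][1] + p[0][2]);
        R_xlen_t k = (R_xlen_t)u + (R_xlen_t)nu * v;
        gu[k] = gx; gv[k] = gy;
        mag[k] = std::sqrt(gx * gx + gy * gy);
        if (mag[k] > mmax) mmax = mag[k];
      }
    if (mmax <= 0) continue;
    const double lo = low_frac * mmax, hi = high_frac * mmax;

    // non-maximum suppression, directions quantized to 0/45/90/135 degrees
    for (int v = 0; v < nv; ++v)
      for (int u = 0; u < nu; ++u) {
        R_xlen_t k = (R_xlen_t)u + (R_xlen_t)nu * v;
        keep[k] = 0; strong[k] = 0;
        double m = mag[k];
        if (m < lo) continue;
        double ang = std::atan2(gv[k], gu[k]);
        if (ang < 0) ang += M_PI;
        int dir = (int)std::floor(ang / (M_PI / 4.0) + 0.5) % 4; // 0,45,90,135
        int iu = 0, iv = 0;
        if (dir == 0) { iu = 1; iv = 0; }
        else if (dir == 1) { iu = 1; iv = 1; }
        else if (dir == 2) { iu = 0; iv = 1; }
        else { iu = -1; iv = 1; }
        double m1 = mag[(R_xlen_t)cl(u + iu, nu - 1) + (R_xlen_t)nu * cl(v + iv, nv - 1)];
        double m2 = mag[(R_xlen_t)cl(u - iu, nu - 1) + (R_xlen_t)nu * cl(v - iv, nv - 1)];
        if (m >= m1 && m >= m2) {
          keep[k] = 1;
          if (m >= hi) strong[k] = 1;
        }
      }

    // hysteresis: weak edges survive only when 8-connected to a strong edge
    std::deque<R_xlen_t> stack;
    std::vector<unsigned char> lab((R_xlen_t)nu * nv, 0);
    for (R_xlen_t k = 0; k < (R_xlen_t)nu * nv; ++k)
      if (strong[k]) { lab[k] = 1; stack.push_back(k); }
    while (!stack.empty()) {
      R_xlen_t k = stack.back(); stack.pop_back();
      int u = (int)(k % nu), v = (int)(k / nu);
      for (int j = -1; j <= 1; ++j)
        for (int i = -1; i <= 1; ++i) {
          int uu = u + i, vv = v + j;
          if (uu < 0 || uu >= nu || vv < 0 || vv >= nv) continue;
          R_xlen_t kk = (R_xlen_t)uu + (R_xlen_t)nu * vv;
          if (keep[kk] && !lab[kk]) { lab[kk] = 1; stack.push_back(kk); }
        }
    }
    for (int v = 0; v < nv; ++v)
      for (int u = 0; u < nu; ++u)
        if (lab[(R_xlen_t)u + (R_xlen_t)nu * v]) out[outIdx(s, u, v)] = 1.0;
  }
  return out;
}
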