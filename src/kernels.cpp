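#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Volumes are stored as numeric arrays with dim = (nz, ny, nx); index
// v[z + nz*(y + ny*x)]. Physical spacing is passed separately where needed.

static inline int reflect(int i, int n) {
  // reflect-101 boundary (a b c | b a) keeps the blur mass-preserving
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * (n - 1) - i;
  }
  return i;
}

static void blur_axis(std::vector<double> &v, int nz, int ny, int nx,
                      int axis, double sigma) {
  if (sigma <= 0) return;
  int radius = (int)std::ceil(4.0 * sigma);
  std::vector<double> k(2 * radius + 1);
  double s = 0.0;
  for (int i = -radius; i <= radius; ++i) {
    k[i + radius] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += k[i + radius];
  }
  for (double &w : k) w /= s;

  std::vector<double> out(v.size(), 0.0);
  // inner loops run over the contiguous z index for cache efficiency
  if (axis == 0) {
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) {
        const double *src = &v[(size_t)nz * (y + (size_t)ny * x)];
        double *dst = &out[(size_t)nz * (y + (size_t)ny * x)];
        for (int z = 0; z < nz; ++z) {
          double acc = 0.0;
          for (int o = -radius; o <= radius; ++o)
            acc += k[o + radius] * src[reflect(z + o, nz)];
          dst[z] = acc;
        }
      }
    }
  } else {
    int len = (axis == 1) ? ny : nx;
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) {
        double *dst = &out[(size_t)nz * (y + (size_t)ny * x)];
        for (int o = -radius; o <= radius; ++o) {
          int ry = y, rx = x;
          if (axis == 1) ry = reflect(y + o, len); else rx = reflect(x + o, len);
          const double *src = &v[(size_t)nz * (ry + (size_t)ny * rx)];
          double w = k[o + radius];
          for (int z = 0; z < nz; ++z) dst[z] += w * src[z];
        }
      }
    }
  }
  v.swap(out);
}

// [[Rcpp::export]]
NumericVector cpp_blur3d(NumericVector arr, IntegerVector dim,
                         NumericVector sigma_vox) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<double> v(arr.begin(), arr.end());
  blur_axis(v, nz, ny, nx, 0, sigma_vox[0]);
  blur_axis(v, nz, ny, nx, 1, sigma_vox[1]);
  blur_axis(v, nz, ny, nx, 2, sigma_vox[2]);
  NumericVector out(v.begin(), v.end());
  out.attr("dim") = dim;
  return out;
}

// Negated 3D Laplacian with physical spacing: blob centres become maxima.
// [[Rcpp::export]]
NumericVector cpp_neg_laplacian(NumericVector arr, IntegerVector dim,
                                NumericVector spacing) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  double wz = 1.0 / (spacing[0] * spacing[0]);
  double wy = 1.0 / (spacing[1] * spacing[1]);
  double wx = 1.0 / (spacing[2] * spacing[2]);
  NumericVector out(arr.size());
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) {
        size_t c = z + (size_t)nz * (y + (size_t)ny * x);
        double v0 = arr[c];
        double lap = 0.0;
        int zm = reflect(z - 1, nz), zp = reflect(z + 1, nz);
        int ym = reflect(y - 1, ny), yp = reflect(y + 1, ny);
        int xm = reflect(x - 1, nx), xp = reflect(x + 1, nx);
        lap += wz * (arr[zm + (size_t)nz * (y + (size_t)ny * x)] +
                     arr[zp + (size_t)nz * (y + (size_t)ny * x)] - 2.0 * v0);
        lap += wy * (arr[z + (size_t)nz * (ym + (size_t)ny * x)] +
                     arr[z + (size_t)nz * (yp + (size_t)ny * x)] - 2.0 * v0);
        lap += wx * (arr[z + (size_t)nz * (y + (size_t)ny * xm)] +
                     arr[z + (size_t)nz * (y + (size_t)ny * xp)] - 2.0 * v0);
        out[c] = -lap;
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}

// Local maxima (26-neighbourhood, >= all neighbours and > at least one, or
// isolated plateau kept once via strictly-greater tie-break on linear index)
// above `threshold`, then greedy suppression so surviving peaks are
// separated by > min_dist in physical units. Returns a matrix with columns
// iz, iy, ix (1-based voxel indices) and the response value, ordered by
// decreasing response.
// [[Rcpp::export]]
NumericMatrix cpp_local_maxima(NumericVector resp, IntegerVector dim,
                               double threshold, NumericVector spacing,
                               double min_dist) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<size_t> cand;
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) {
        size_t c = z + (size_t)nz * (y + (size_t)ny * x);
        double v0 = resp[c];
        if (!(v0 > threshold)) continue;
        bool ismax = true;
        for (int dz = -1; dz <= 1 && ismax; ++dz) {
          for (int dy = -1; dy <= 1 && ismax; ++dy) {
            for (int dx = -1; dx <= 1; ++dx) {
              if (dz == 0 && dy == 0 && dx == 0) continue;
              int z2 = z + dz, y2 = y + dy, x2 = x + dx;
              if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny ||
                  x2 < 0 || x2 >= nx) continue;
              size_t c2 = z2 + (size_t)nz * (y2 + (size_t)ny * x2);
              double v2 = resp[c2];
              if (v2 > v0 || (v2 == v0 && c2 < c)) { ismax = false; break; }
            }
          }
        }
        if (ismax) cand.push_back(c);
      }
    }
  }
  std::sort(cand.begin(), cand.end(), [&](size_t a, size_t b) {
    if (resp[a] != resp[b]) return resp[a] > resp[b];
    return a < b;
  });
  double dz = spacing[0], dy = spacing[1], dx = spacing[2];
  std::vector<size_t> keep;
  std::vector<double> kz, ky, kx;
  double md2 = min_dist * min_dist;
  for (size_t c : cand) {
    int x = (int)(c / ((size_t)nz * ny));
    int y = (int)((c / nz) % ny);
    int z = (int)(c % nz);
    double pz = z * dz, py = y * dy, px = x * dx;
    bool ok = true;
    for (size_t j = 0; j < keep.size(); ++j) {
      double ddz = pz - kz[j], ddy = py - ky[j], ddx = px - kx[j];
      if (ddz * ddz + ddy * ddy + ddx * ddx <= md2) { ok = false; break; }
    }
    if (ok) {
      keep.push_back(c);
      kz.push_back(pz); ky.push_back(py); kx.push_back(px);
    }
  }
  NumericMatrix out(keep.size(), 4);
  for (size_t j = 0; j < keep.size(); ++j) {
    size_t c = keep[j];
    int x = (int)(c / ((size_t)nz * ny));
    int y = (int)((c / nz) % ny);
    int z = (int)(c % nz);
    out(j, 0) = z + 1; out(j, 1) = y + 1; out(j, 2) = x + 1;
    out(j, 3) = resp[c];
  }
  colnames(out) = CharacterVector::create("iz", "iy", "ix", "value");
  return out;
}

// Exact nearest-neighbour distances source -> target via a uniform grid
// with expanding ring search. Exactness: a ring is only abandoned once its
// minimum possible distance exceeds the best distance found so far.
// [[Rcpp::export]]
NumericVector cpp_nn_dist(NumericMatrix src, NumericMatrix tgt) {
  int n = src.nrow(), m = tgt.nrow();
  NumericVector out(n);
  if (m == 0) stop("empty target set");
  if (m <= 32 || n <= 4) { // brute force for tiny problems
    for (int i = 0; i < n; ++i) {
      double best = R_PosInf;
      for (int j = 0; j < m; ++j) {
        double d0 = src(i, 0) - tgt(j, 0);
        double d1 = src(i, 1) - tgt(j, 1);
        double d2 = src(i, 2) - tgt(j, 2);
        double d = d0 * d0 + d1 * d1 + d2 * d2;
        if (d < best) best = d;
      }
      out[i] = std::sqrt(best);
    }
    return out;
  }
  double lo[3], hi[3];
  for (int k = 0; k < 3; ++k) {
    lo[k] = R_PosInf; hi[k] = R_NegInf;
    for (int j = 0; j < m; ++j) {
      lo[k] = std::min(lo[k], tgt(j, k));
      hi[k] = std::max(hi[k], tgt(j, k));
    }
    for (int i = 0; i < n; ++i) {
      lo[k] = std::min(lo[k], src(i, k));
      hi[k] = std::max(hi[k], src(i, k));
    }
  }
  double vol = 1.0;
  for (int k = 0; k < 3; ++k) vol *= std::max(hi[k] - lo[k], 1e-9);
  double cell = std::cbrt(vol / m);           // ~1 target per cell
  int ng[3];
  for (int k = 0; k < 3; ++k)
    ng[k] = std::max(1, (int)std::floor((hi[k] - lo[k]) / cell) + 1);
  size_t ncell = (size_t)ng[0] * ng[1] * ng[2];
  std::vector<std::vector<int> > bucket(ncell);
  auto cellof = [&](double a, int k) {
    int c = (int)std::floor((a - lo[k]) / cell);
    if (c < 0) c = 0;
    if (c >= ng[k]) c = ng[k] - 1;
    return c;
  };
  for (int j = 0; j < m; ++j) {
    size_t c = cellof(tgt(j, 0), 0) +
               (size_t)ng[0] * (cellof(tgt(j, 1), 1) +
               (size_t)ng[1] * cellof(tgt(j, 2), 2));
    bucket[c].push_back(j);
  }
  int maxring = std::max(std::max(ng[0], ng[1]), ng[2]);
  for (int i = 0; i < n; ++i) {
    double p0 = src(i, 0), p1 = src(i, 1), p2 = src(i, 2);
    int c0 = cellof(p0, 0), c1 = cellof(p1, 1), c2 = cellof(p2, 2);
    double best = R_PosInf;
    for (int r = 0; r <= maxring; ++r) {
      // lower bound on distance from p to any cell in ring r
      if (r > 0) {
        double lb = (r - 1) * cell;
        if (lb * lb > best) break;
      }
      bool any = false;
      for (int a = c0 - r; a <= c0 + r; ++a) {
        if (a < 0 || a >= ng[0]) continue;
        for (int b = c1 - r; b <= c1 + r; ++b) {
          if (b < 0 || b >= ng[1]) continue;
          for (int c = c2 - r; c <= c2 + r; ++c) {
            if (c < 0 || c >= ng[2]) continue;
            if (std::max(std::max(std::abs(a - c0), std::abs(b - c1)),
                         std::abs(c - c2)) != r) continue;
            any = true;
            const std::vector<int> &bk =
              bucket[a + (size_t)ng[0] * (b + (size_t)ng[1] * c)];
            for (int j : bk) {
              double d0 = p0 - tgt(j, 0);
              double d1 = p1 - tgt(j, 1);
              double d2 = p2 - tgt(j, 2);
              double d = d0 * d0 + d1 * d1 + d2 * d2;
              if (d < best) best = d;
            }
          }
        }
      }
      if (!any && r >= maxring) break;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
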