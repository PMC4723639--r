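#include <Rcpp.h>
#include <vector>
#include <array>
#include <queue>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Offsets for 6/18/26 voxel connectivity.
static std::vector<std::array<int, 3>> neighbor_offsets(int connectivity) {
  std::vector<std::array<int, 3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (manh == 0) continue;
        if (connectivity == 6 && manh > 1) continue;
        if (connectivity == 18 && manh > 2) continue;
        offs.push_back({dx, dy, dz});
      }
  return offs;
}

// Label connected components of a 3-D logical grid. Labels are assigned in
// increasing order of the first (column-major) voxel of each component, so
// component 1 always holds the lexicographically smallest seed voxel.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector labels(n, 0);
  std::vector<std::array<int, 3>> offs = neighbor_offsets(connectivity);
  int next_label = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || labels[start] != 0) continue;
    ++next_label;
    labels[start] = next_label;
    q.push(start);
    while (!q.empty()) {
      R_xlen_t idx = q.front();
      q.pop();
      int x = (int)(idx % nx);
      int y = (int)((idx / nx) % ny);
      int z = (int)(idx / ((R_xlen_t)nx * ny));
      for (size_t k = 0; k < offs.size(); ++k) {
        int xx = x + offs[k][0], yy = y + offs[k][1], zz = z + offs[k][2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t jdx = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (mask[jdx] && labels[jdx] == 0) {
          labels[jdx] = next_label;
          q.push(jdx);
        }
      }
    }
  }
  labels.attr("n_components") = next_label;
  return labels;
}

// One-dimensional squared distance transform (lower envelope of parabolas)
// with grid weight s2 = spacing^2. Source values may be +Inf (no site).
static void dt1d(const double* f, double* d, int n, double s2, int* v,
                 double* z) {
  const double inf = std::numeric_limits<double>::infinity();
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] == inf) continue;
    if (k < 0) {
      k = 0;
      v[0] = q;
      z[0] = -inf;
      z[1] = inf;
      continue;
    }
    double s = ((f[q] + s2 * q * q) - (f[v[k]] + s2 * v[k] * v[k])) /
               (2.0 * s2 * (q - v[k]));
    while (s <= z[k]) {
      --k;
      s = ((f[q] + s2 * q * q) - (f[v[k]] + s2 * v[k] * v[k])) /
          (2.0 * s2 * (q - v[k]));
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = inf;
  }
  if (k < 0) {
    for (int q = 0; q < n; ++q) d[q] = inf;
    return;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (double)q - (double)v[k];
    d[q] = s2 * dq * dq + f[v[k]];
  }
}

// Squared Euclidean distance (mm^2) from every voxel center to the nearest
// TRUE voxel center, honouring anisotropic spacing. Voxels are Inf when the
// mask is empty.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dims,
                         NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double inf = std::numeric_limits<double>::infinity();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? 0.0 : inf;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // axis 0 (x)
  double s2 = spacing[0] * spacing[0];
  for (int zz = 0; zz < nz; ++zz)
    for (int yy = 0; yy < ny; ++yy) {
      R_xlen_t base = (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
      bool any = false;
      for (int xx = 0; xx < nx; ++xx) {
        f[xx] = out[base + xx];
        if (f[xx] < inf) any = true;
      }
      if (!any) continue;
      dt1d(f.data(), d.data(), nx, s2, v.data(), z.data());
      for (int xx = 0; xx < nx; ++xx) out[base + xx] = d[xx];
    }
  // axis 1 (y)
  s2 = spacing[1] * spacing[1];
  for (int zz = 0; zz < nz; ++zz)
    for (int xx = 0; xx < nx; ++xx) {
      R_xlen_t base = xx + (R_xlen_t)nx * ny * zz;
      bool any = false;
      for (int yy = 0; yy < ny; ++yy) {
        f[yy] = out[base + (R_xlen_t)nx * yy];
        if (f[yy] < inf) any = true;
      }
      if (!any) continue;
      dt1d(f.data(), d.data(), ny, s2, v.data(), z.data());
      for (int yy = 0; yy < ny; ++yy) out[base + (R_xlen_t)nx * yy] = d[yy];
    }
  // axis 2 (z)
  s2 = spacing[2] * spacing[2];
  for (int yy = 0; yy < ny; ++yy)
    for (int xx = 0; xx < nx; ++xx) {
      R_xlen_t base = xx + (R_xlen_t)nx * yy;
      bool any = false;
      for (int zz = 0; zz < nz; ++zz) {
        f[zz] = out[base + (R_xlen_t)nx * ny * zz];
        if (f[zz] < inf) any = true;
      }
      if (!any) continue;
      dt1d(f.data(), d.data(), nz, s2, v.data(), z.data());
      for (int zz = 0; zz < nz; ++zz)
        out[base + (R_xlen_t)nx * ny * zz] = d[zz];
    }
  return out;
}

// Separable Gaussian blur; sigma is given in voxels per axis. Kernels are
// truncated at 4 sigma and renormalised at the grid edges (replicate-free
// normalisation keeps flat regions flat).
// [[Rcpp::export]]
NumericVector cpp_gauss_blur(NumericVector vol, IntegerVector dims,
                             NumericVector sigma_vox) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector cur = clone(vol);
  for (int axis = 0; axis < 3; ++axis) {
    double sig = sigma_vox[axis];
    if (sig <= 0) continue;
    int radius = (int)std::ceil(4.0 * sig);
    std::vector<double> w(2 * radius + 1);
    for (int i = -radius; i <= radius; ++i)
      w[i + radius] = std::exp(-0.5 * (double)i * i / (sig * sig));
    NumericVector nxt(n);
    int len = (axis == 0) ? nx : (axis == 1) ? ny : nz;
    R_xlen_t stride = (axis == 0) ? 1
                      : (axis == 1) ? (R_xlen_t)nx
                                    : (R_xlen_t)nx * ny;
    // iterate over all lines along `axis`
    int na = (axis == 0) ? ny : nx;
    int nb = (axis == 2) ? ny : nz;
    R_xlen_t stra = (axis == 0) ? (R_xlen_t)nx : 1;
    R_xlen_t strb = (axis == 2) ? (R_xlen_t)nx : (R_xlen_t)nx * ny;
    for (int b = 0; b < nb; ++b)
      for (int a = 0; a < na; ++a) {
        R_xlen_t base = a * stra + b * strb;
        for (int p = 0; p < len; ++p) {
          double acc = 0.0, norm = 0.0;
          int lo = std::max(0, p - radius), hi = std::min(len - 1, p + radius);
          for (int q = lo; q <= hi; ++q) {
            double wt = w[q - p + radius];
            acc += wt * cur[base + (R_xlen_t)q * stride];
            norm += wt;
          }
          nxt[base + (R_xlen_t)p * stride] = acc / norm;
        }
      }
    cur = nxt;
  }
  return cur;
}
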