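#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Column-major linear index, 0-based: i + nx*(j + ny*k)

// ---------------------------------------------------------------------------
// 26-connected component labelling of voxels equal to `target`.
// Returns integer array: 0 for non-target voxels, 1..ncomp component ids.
// Iterative stack-based flood fill; component ids are assigned in raster
// order of the first voxel encountered, so labelling is deterministic.
// [[Rcpp::export]]
IntegerVector cpp_label_components_26(IntegerVector labels, IntegerVector dims,
                                      int target) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector out(n, 0);
  std::vector<R_xlen_t> stack;
  int comp = 0;

  for (R_xlen_t start = 0; start < n; ++start) {
    if (labels[start] != target || out[start] != 0) continue;
    ++comp;
    stack.clear();
    stack.push_back(start);
    out[start] = comp;
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int k = (int)(v / ((R_xlen_t)nx * ny));
      int rem = (int)(v % ((R_xlen_t)nx * ny));
      int j = rem / nx;
      int i = rem % nx;
      for (int dk = -1; dk <= 1; ++dk) {
        int kk = k + dk;
        if (kk < 0 || kk >= nz) continue;
        for (int dj = -1; dj <= 1; ++dj) {
          int jj = j + dj;
          if (jj < 0 || jj >= ny) continue;
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            int ii = i + di;
            if (ii < 0 || ii >= nx) continue;
            R_xlen_t w = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
            if (labels[w] == target && out[w] == 0) {
              out[w] = comp;
              stack.push_back(w);
            }
          }
        }
      }
    }
  }
  out.attr("ncomp") = comp;
  return out;
}

// ---------------------------------------------------------------------------
// Exact 1D squared-distance transform (Felzenszwalb & Huttenlocher).
// Infinite (absent) parabolas are skipped, so the lower envelope contains
// only finite sources; with z[0] = -Inf the stack index k never underflows.
static void dt1d(const double* f, double* d, int n,
                 std::vector<int>& v, std::vector<double>& z) {
  const double INF = std::numeric_limits<double>::infinity();
  int q0 = -1;
  for (int q = 0; q < n; ++q)
    if (f[q] < INF) { q0 = q; break; }
  if (q0 < 0) {
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  int k = 0;
  v[0] = q0;
  z[0] = -INF;
  z[1] = INF;
  auto intersect = [&](int q, int p) {
    return ((f[q] + (double)q * q) - (f[p] + (double)p * p)) /
           (2.0 * q - 2.0 * p);
  };
  for (int q = q0 + 1; q < n; ++q) {
    if (f[q] == INF) continue;
    double s = intersect(q, v[k]);
    while (s <= z[k]) {
      --k;
      s = intersect(q, v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (double)q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact Euclidean distance transform from a seed mask (isotropic voxels).
// Returns distances in voxel units (multiply by voxel size for physical).
// [[Rcpp::export]]
NumericVector cpp_edt3d(LogicalVector seed, IntegerVector dims) {
  const double INF = std::numeric_limits<double>::infinity();
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector d(n);
  for (R_xlen_t i = 0; i < n; ++i) d[i] = seed[i] ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), g(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      for (int i = 0; i < nx; ++i) f[i] = d[base + i];
      dt1d(f.data(), g.data(), nx, v, z);
      for (int i = 0; i < nx; ++i) d[base + i] = g[i];
    }
  // pass along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + (R_xlen_t)nx * ny * (R_xlen_t)k;
      for (int j = 0; j < ny; ++j) f[j] = d[base + (R_xlen_t)nx * j];
      dt1d(f.data(), g.data(), ny, v, z);
      for (int j = 0; j < ny; ++j) d[base + (R_xlen_t)nx * j] = g[j];
    }
  // pass along z
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + (R_xlen_t)nx * j;
      for (int k = 0; k < nz; ++k) f[k] = d[base + nxy * k];
      dt1d(f.data(), g.data(), nz, v, z);
      for (int k = 0; k < nz; ++k) d[base + nxy * k] = g[k];
    }

  for (R_xlen_t i = 0; i < n; ++i)
    d[i] = (d[i] == INF) ? NA_REAL : std::sqrt(d[i]);
  return d;
}

// ---------------------------------------------------------------------------
// Separable Gaussian blur with reflecting boundaries; sigma in voxels.
// [[Rcpp::export]]
NumericVector cpp_gauss_blur3d(NumericVector x, IntegerVector dims,
                               double sigma) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (sigma <= 0) return clone(x);
  int rad = (int)std::ceil(3.0 * sigma);
  std::vector<double> ker(2 * rad + 1);
  double s = 0;
  for (int i = -rad; i <= rad; ++i) {
    ker[i + rad] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += ker[i + rad];
  }
  for (double& w : ker) w /= s;

  NumericVector a = clone(x), b(n);

  auto convolve_axis = [&](NumericVector& src, NumericVector& dst,
                           int axis) {
    int len = (axis == 0) ? nx : (axis == 1) ? ny : nz;
    R_xlen_t stride = (axis == 0) ? 1
                    : (axis == 1) ? (R_xlen_t)nx
                    : (R_xlen_t)nx * ny;
    // iterate over all lines along `axis`
    int na = (axis == 0) ? ny : nx;
    int nb = (axis == 2) ? ny : nz;
    for (int bidx = 0; bidx < nb; ++bidx)
      for (int aidx = 0; aidx < na; ++aidx) {
        R_xlen_t base;
        if (axis == 0)
          base = (R_xlen_t)nx * (aidx + (R_xlen_t)ny * bidx);
        else if (axis == 1)
          base = aidx + (R_xlen_t)nx * ny * (R_xlen_t)bidx;
        else
          base = aidx + (R_xlen_t)nx * bidx;
        for (int q = 0; q < len; ++q) {
          double acc = 0;
          for (int t = -rad; t <= rad; ++t) {
            int p = q + t;
            if (p < 0) p = -p - 1;          // reflect
            if (p >= len) p = 2 * len - p - 1;
            if (p < 0) p = 0;               // tiny-axis guard
            if (p >= len) p = len - 1;
            acc += ker[t + rad] * src[base + stride * p];
          }
          dst[base + stride * q] = acc;
        }
      }
  };

  convolve_axis(a, b, 0);
  convolve_axis(b, a, 1);
  convolve_axis(a, b, 2);
  return b;
}
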