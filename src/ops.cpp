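#include <Rcpp.h>
#include <queue>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Voxel kernels shared by the registration, morphology and metrics layers.
// All volumes are passed as flat vectors in R's column-major order
// (first index fastest) with dim = c(nx, ny, nz); indices are 0-based here.

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// Trilinear resampling. For every voxel of the output grid the continuous
// source index is A %*% (x,y,z) + b; samples outside the source volume
// contribute zero (background).
// [[Rcpp::export]]
NumericVector cpp_resample_trilinear(NumericVector vol, IntegerVector din,
                                     IntegerVector dout, NumericMatrix A,
                                     NumericVector b) {
  const int nxi = din[0], nyi = din[1], nzi = din[2];
  const int nxo = dout[0], nyo = dout[1], nzo = dout[2];
  NumericVector out((double)nxo * nyo * nzo);
  const double a00 = A(0,0), a01 = A(0,1), a02 = A(0,2);
  const double a10 = A(1,0), a11 = A(1,1), a12 = A(1,2);
  const double a20 = A(2,0), a21 = A(2,1), a22 = A(2,2);
  int o = 0;
  for (int z = 0; z < nzo; ++z) {
    for (int y = 0; y < nyo; ++y) {
      const double sx0 = a01 * y + a02 * z + b[0];
      const double sy0 = a11 * y + a12 * z + b[1];
      const double sz0 = a21 * y + a22 * z + b[2];
      for (int x = 0; x < nxo; ++x, ++o) {
        const double sx = a00 * x + sx0;
        const double sy = a10 * x + sy0;
        const double sz = a20 * x + sz0;
        if (sx <= -1.0 || sy <= -1.0 || sz <= -1.0 ||
            sx >= nxi || sy >= nyi || sz >= nzi) continue;
        const int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy),
                  z0 = (int)std::floor(sz);
        const double fx = sx - x0, fy = sy - y0, fz = sz - z0;
        double acc = 0.0;
        for (int dz = 0; dz <= 1; ++dz) {
          const int zz = z0 + dz;
          if (zz < 0 || zz >= nzi) continue;
          const double wz = dz ? fz : 1.0 - fz;
          for (int dy = 0; dy <= 1; ++dy) {
            const int yy = y0 + dy;
            if (yy < 0 || yy >= nyi) continue;
            const double wy = dy ? fy : 1.0 - fy;
            for (int dx = 0; dx <= 1; ++dx) {
              const int xx = x0 + dx;
              if (xx < 0 || xx >= nxi) continue;
              const double wx = dx ? fx : 1.0 - fx;
              acc += wx * wy * wz * vol[idx3(xx, yy, zz, nxi, nyi)];
            }
          }
        }
        out[o] = acc;
      }
    }
  }
  return out;
}

// 1D squared-distance transform (lower envelope of parabolas) on samples at
// positions i*w; f is overwritten with the transform.
static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& zb,
                 int n, double w) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  zb[0] = -INF;
  zb[1] = INF;
  const double w2 = w * w;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    if (f[v[0]] == INF && k == 0) { v[0] = q; continue; }
    double s;
    while (true) {
      const int p = v[k];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * (q - p));
      if (s <= zb[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zb[k] = s;
    zb[k + 1] = INF;
  }
  if (f[v[0]] == INF) {  // no finite sample on this line
    for (int q = 0; q < n; ++q) d[q] = INF;
  } else {
    int j = 0;
    for (int q = 0; q < n; ++q) {
      while (zb[j + 1] < q) ++j;
      const double dq = w * (q - v[j]);
      d[q] = dq * dq + f[v[j]];
    }
  }
  for (int q = 0; q < n; ++q) f[q] = d[q];
}

// Exact Euclidean distance (mm) from every voxel centre to the nearest site
// voxel centre, honouring anisotropic spacing (Felzenszwalb-Huttenlocher).
// [[Rcpp::export]]
NumericVector cpp_edt(IntegerVector sites, IntegerVector dim,
                      NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double INF = std::numeric_limits<double>::infinity();
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = sites[i] ? 0.0 : INF;
  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), zb(nmax + 1);
  std::vector<int> v(nmax);
  // pass along x
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      const int base = idx3(0, y, z, nx, ny);
      for (int x = 0; x < nx; ++x) f[x] = g[base + x];
      dt1d(f, d, v, zb, nx, spacing[0]);
      for (int x = 0; x < nx; ++x) g[base + x] = f[x];
    }
  // pass along y
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) f[y] = g[idx3(x, y, z, nx, ny)];
      dt1d(f, d, v, zb, ny, spacing[1]);
      for (int y = 0; y < ny; ++y) g[idx3(x, y, z, nx, ny)] = f[y];
    }
  // pass along z
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      for (int z = 0; z < nz; ++z) f[z] = g[idx3(x, y, z, nx, ny)];
      dt1d(f, d, v, zb, nz, spacing[2]);
      for (int z = 0; z < nz; ++z) g[idx3(x, y, z, nx, ny)] = f[z];
    }
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = (g[i] == INF) ? R_PosInf : std::sqrt(g[i]);
  return out;
}

// Connected-component labelling under 6/18/26 connectivity (BFS).
// Labels are assigned in raster-scan order of each component's first voxel,
// so the labelling is deterministic.
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector mask, IntegerVector dim,
                                   int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n);
  std::vector<std::array<int,3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        const int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        offs.push_back({dx, dy, dz});
      }
  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i]) continue;
    lab[i] = ++next;
    q.push(i);
    while (!q.empty()) {
      const R_xlen_t cur = q.front(); q.pop();
      const int x = cur % nx, y = (cur / nx) % ny, z = cur / ((R_xlen_t)nx * ny);
      for (const auto& o : offs) {
        const int xx = x + o[0], yy = y + o[1], zz = z + o[2];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
          continue;
        const R_xlen_t j = idx3(xx, yy, zz, nx, ny);
        if (mask[j] && !lab[j]) { lab[j] = next; q.push(j); }
      }
    }
  }
  return lab;
}

// Count of foreground voxels inside a neighbourhood given by integer offsets
// (k x 3 matrix); voxels outside the volume count as background.
// mode 0: raw count; mode 1: 1 iff all offsets foreground (erosion);
// mode 2: 1 iff any offset foreground (dilation).
// [[Rcpp::export]]
IntegerVector cpp_neighborhood(IntegerVector mask, IntegerVector dim,
                               IntegerMatrix offsets, int mode) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const int k = offsets.nrow();
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const int x = i % nx, y = (i / nx) % ny, z = i / ((R_xlen_t)nx * ny);
    int cnt = 0;
    bool all = true, any = false;
    for (int j = 0; j < k; ++j) {
      const int xx = x + offsets(j, 0), yy = y + offsets(j, 1),
                zz = z + offsets(j, 2);
      int val = 0;
      if (xx >= 0 && yy >= 0 && zz >= 0 && xx < nx && yy < ny && zz < nz)
        val = mask[idx3(xx, yy, zz, nx, ny)];
      if (val) { ++cnt; any = true; } else all = false;
      if (mode == 1 && !all) break;
      if (mode == 2 && any) break;
    }
    if (mode == 0) out[i] = cnt;
    else if (mode == 1) out[i] = all ? 1 : 0;
    else out[i] = any ? 1 : 0;
  }
  return out;
}

// Separable Gaussian smoothing; sigma per axis in voxel units, kernel
// truncated at 3 sigma and renormalised at the borders.
// [[Rcpp::export]]
NumericVector cpp_smooth_gaussian(NumericVector vol, IntegerVector dim,
                                  NumericVector sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> cur(vol.begin(), vol.end()), nxt(n);
  const int dims[3] = {nx, ny, nz};
  for (int ax = 0; ax < 3; ++ax) {
    const double s = sigma[ax];
    if (s <= 0) continue;
    const int r = std::max(1, (int)std::ceil(3.0 * s));
    std::vector<double> kern(2 * r + 1);
    for (int i = -r; i <= r; ++i)
      kern[i + r] = std::exp(-0.5 * (double)i * i / (s * s));
    const int len = dims[ax];
    R_xlen_t stride = 1;
    for (int a = 0; a < ax; ++a) stride *= dims[a];
    for (R_xlen_t i = 0; i < n; ++i) {
      int coord;
      if (ax == 0) coord = i % nx;
      else if (ax == 1) coord = (i / nx) % ny;
      else coord = i / ((R_xlen_t)nx * ny);
      double acc = 0.0, wsum = 0.0;
      const int lo = std::max(-r, -coord), hi = std::min(r, len - 1 - coord);
      for (int off = lo; off <= hi; ++off) {
        const double w = kern[off + r];
        acc += w * cur[i + (R_xlen_t)off * stride];
        wsum += w;
      }
      nxt[i] = acc / wsum;
    }
    cur.swap(nxt);
  }
  return NumericVector(cur.begin(), cur.end());
}
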