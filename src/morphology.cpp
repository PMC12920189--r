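#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <limits>

using namespace Rcpp;

// 3D connected-component labeling by breadth-first search.
// connectivity: 6 (faces), 18 (faces+edges), or 26 (faces+edges+corners).
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dim");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  // neighbor offsets
  std::vector<int> dxs, dys, dzs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manhattan = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manhattan > 1) continue;
        if (connectivity == 18 && manhattan > 2) continue;
        dxs.push_back(dx); dys.push_back(dy); dzs.push_back(dz);
      }

  IntegerVector labels(n, 0);
  int current = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || labels[start] != 0) continue;
    ++current;
    labels[start] = current;
    q.push(start);
    while (!q.empty()) {
      R_xlen_t v = q.front(); q.pop();
      int x = (int)(v % nx);
      int y = (int)((v / nx) % ny);
      int z = (int)(v / ((R_xlen_t)nx * ny));
      for (size_t k = 0; k < dxs.size(); ++k) {
        int xx = x + dxs[k], yy = y + dys[k], zz = z + dzs[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t w = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
        if (mask[w] && labels[w] == 0) {
          labels[w] = current;
          q.push(w);
        }
      }
    }
  }
  return labels;
}

// 1D squared distance transform of sampled function f at positions i*s
// (Felzenszwalb & Huttenlocher lower-envelope-of-parabolas).
static void dt1d(std::vector<double> &f, double s, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z) {
  const int n = (int)f.size();
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  const double s2 = s * s;
  for (int q = 1; q < n; ++q) {
    double fq = f[q];
    double sInter;
    while (true) {
      int p = v[k];
      sInter = ((fq + s2 * q * q) - (f[p] + s2 * p * p)) / (2.0 * s2 * (q - p));
      if (sInter <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = sInter;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    int p = v[k];
    double dq = (double)(q - p) * s;
    d[q] = dq * dq + f[p];
  }
}

// Euclidean distance transform: for every voxel, the distance in mm to the
// nearest TRUE voxel of `mask`, honouring anisotropic spacing. All-false mask
// gives Inf everywhere.
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dim,
                      NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dim");
  // large finite sentinel instead of Inf: keeps the parabola intersections
  // finite when a scan line mixes reached and unreached voxels
  const double INF = 1e15;

  NumericVector d2(n);
  for (R_xlen_t i = 0; i < n; ++i) d2[i] = mask[i] ? 0.0 : INF;

  int maxdim = std::max(nx, std::max(ny, nz));
  std::vector<double> f(maxdim), dbuf(maxdim), z(maxdim + 1);
  std::vector<int> v(maxdim);

  // pass along x
  for (int zc = 0; zc < nz; ++zc)
    for (int yc = 0; yc < ny; ++yc) {
      R_xlen_t base = (R_xlen_t)zc * nx * ny + (R_xlen_t)yc * nx;
      bool any = false;
      for (int x = 0; x < nx; ++x) { f[x] = d2[base + x]; if (f[x] < INF) any = true; }
      if (!any) continue;
      f.resize(nx); dt1d(f, spacing[0], dbuf, v, z); f.resize(maxdim);
      for (int x = 0; x < nx; ++x) d2[base + x] = dbuf[x];
    }
  // pass along y
  for (int zc = 0; zc < nz; ++zc)
    for (int xc = 0; xc < nx; ++xc) {
      R_xlen_t base = (R_xlen_t)zc * nx * ny + xc;
      bool any = false;
      for (int y = 0; y < ny; ++y) { f[y] = d2[base + (R_xlen_t)y * nx]; if (f[y] < INF) any = true; }
      if (!any) continue;
      f.resize(ny); dt1d(f, spacing[1], dbuf, v, z); f.resize(maxdim);
      for (int y = 0; y < ny; ++y) d2[base + (R_xlen_t)y * nx] = dbuf[y];
    }
  // pass along z
  for (int yc = 0; yc < ny; ++yc)
    for (int xc = 0; xc < nx; ++xc) {
      R_xlen_t base = (R_xlen_t)yc * nx + xc;
      bool any = false;
      for (int zc = 0; zc < nz; ++zc) { f[zc] = d2[base + (R_xlen_t)zc * nx * ny]; if (f[zc] < INF) any = true; }
      if (!any) continue;
      f.resize(nz); dt1d(f, spacing[2], dbuf, v, z); f.resize(maxdim);
      for (int zc = 0; zc < nz; ++zc) d2[base + (R_xlen_t)zc * nx * ny] = dbuf[zc];
    }

  for (R_xlen_t i = 0; i < n; ++i)
    d2[i] = (d2[i] >= 1e14) ? R_PosInf : std::sqrt(d2[i]);
  return d2;
}

// Trilinear / nearest-neighbour resampling of a 3D array onto a new grid.
// Output voxel (i,j,k) samples input at continuous voxel coordinate
// ((i + 0.5) * out_sp / in_sp - 0.5) per axis (centre-aligned grids).
// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector values, IntegerVector dim,
                           NumericVector in_spacing, IntegerVector out_dim,
                           NumericVector out_spacing, int order) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int mx = out_dim[0], my = out_dim[1], mz = out_dim[2];
  NumericVector out((R_xlen_t)mx * my * mz);
  const double rx = out_spacing[0] / in_spacing[0];
  const double ry = out_spacing[1] / in_spacing[1];
  const double rz = out_spacing[2] / in_spacing[2];

  for (int k = 0; k < mz; ++k) {
    double zc = (k + 0.5) * rz - 0.5;
    for (int j = 0; j < my; ++j) {
      double yc = (j + 0.5) * ry - 0.5;
      for (int i = 0; i < mx; ++i) {
        double xc = (i + 0.5) * rx - 0.5;
        double val;
        if (order == 0) {
          int xi = (int)std::lround(xc), yi = (int)std::lround(yc), zi = (int)std::lround(zc);
          xi = std::min(std::max(xi, 0), nx - 1);
          yi = std::min(std::max(yi, 0), ny - 1);
          zi = std::min(std::max(zi, 0), nz - 1);
          val = values[(R_xlen_t)zi * nx * ny + (R_xlen_t)yi * nx + xi];
        } else {
          double xcl = std::min(std::max(xc, 0.0), (double)(nx - 1));
          double ycl = std::min(std::max(yc, 0.0), (double)(ny - 1));
          double zcl = std::min(std::max(zc, 0.0), (double)(nz - 1));
          int x0 = (int)std::floor(xcl), y0 = (int)std::floor(ycl), z0 = (int)std::floor(zcl);
          int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1), z1 = std::min(z0 + 1, nz - 1);
          double fx = xcl - x0, fy = ycl - y0, fz = zcl - z0;
          auto at = [&](int x, int y, int zz) {
            return values[(R_xlen_t)zz * nx * ny + (R_xlen_t)y * nx + x];
          };
          double c00 = at(x0, y0, z0) * (1 - fx) + at(x1, y0, z0) * fx;
          double c10 = at(x0, y1, z0) * (1 - fx) + at(x1, y1, z0) * fx;
          double c01 = at(x0, y0, z1) * (1 - fx) + at(x1, y0, z1) * fx;
          double c11 = at(x0, y1, z1) * (1 - fx) + at(x1, y1, z1) * fx;
          double c0 = c00 * (1 - fy) + c10 * fy;
          double c1 = c01 * (1 - fy) + c11 * fy;
          val = c0 * (1 - fz) + c1 * fz;
        }
        out[(R_xlen_t)k * mx * my + (R_xlen_t)j * mx + i] = val;
      }
    }
  }
  return out;
}
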