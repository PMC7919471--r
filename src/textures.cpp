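// Texture-matrix accumulation kernels.
//
// All functions take a 3D integer grid `levels` (flattened x-fastest, with
// `dim` = c(nx, ny, nz)) where 0 marks out-of-mask voxels and values >= 1
// are discretized gray levels. Matrices are merged over the 13 unique 3D
// directions at Chebyshev distance 1 (one matrix, not per-direction
// averages), which is the convention of the open-source radiomics toolbox
// lineage this package follows.

#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

static const int NDIR = 13;
static void directions(int d[NDIR][3]) {
  int n = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        if (dz > 0 || (dz == 0 && dy > 0) || (dz == 0 && dy == 0 && dx > 0)) {
          d[n][0] = dx; d[n][1] = dy; d[n][2] = dz; ++n;
        }
      }
}

static inline int at(const IntegerVector& lv, int x, int y, int z,
                     int nx, int ny, int nz) {
  if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz) return -1;
  return lv[x + nx * (y + (R_xlen_t)ny * z)];
}

// [[Rcpp::export]]
NumericMatrix cpp_glcm(IntegerVector levels, IntegerVector dim, int nlev) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int dirs[NDIR][3]; directions(dirs);
  NumericMatrix m(nlev, nlev);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int a = at(levels, x, y, z, nx, ny, nz);
        if (a <= 0) continue;
        for (int k = 0; k < NDIR; ++k) {
          int b = at(levels, x + dirs[k][0], y + dirs[k][1], z + dirs[k][2],
                     nx, ny, nz);
          if (b <= 0) continue;
          m(a - 1, b - 1) += 1.0;   // symmetric: count both orders
          m(b - 1, a - 1) += 1.0;
        }
      }
  return m;
}

// Run-length counts: rows = gray level, cols = run length. `dirvec` is an
// ndir x 3 matrix of direction offsets (the merged default is the 13 unique
// 3D directions; single directions support 1D closed-form checks).
// [[Rcpp::export]]
NumericMatrix cpp_glrlm(IntegerVector levels, IntegerVector dim, int nlev,
                        IntegerMatrix dirvec) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int maxlen = std::max(std::max(nx, ny), nz);
  NumericMatrix m(nlev, maxlen);
  for (int k = 0; k < dirvec.nrow(); ++k) {
    int dx = dirvec(k, 0), dy = dirvec(k, 1), dz = dirvec(k, 2);
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int a = at(levels, x, y, z, nx, ny, nz);
          if (a <= 0) continue;
          // only start a run where the previous voxel breaks it
          if (at(levels, x - dx, y - dy, z - dz, nx, ny, nz) == a) continue;
          int len = 1;
          int cx = x + dx, cy = y + dy, cz = z + dz;
          while (at(levels, cx, cy, cz, nx, ny, nz) == a) {
            ++len; cx += dx; cy += dy; cz += dz;
          }
          if (len > m.ncol()) stop("run longer than grid extent");
          m(a - 1, len - 1) += 1.0;
        }
  }
  return m;
}

// 26-connected components of equal gray level; returns labels (0 outside).
// [[Rcpp::export]]
IntegerVector cpp_label_zones(IntegerVector levels, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  int next = 0;
  std::queue<int> q;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (levels[i] <= 0 || lab[i] != 0) continue;
    ++next;
    lab[i] = next; q.push((int)i);
    int lev = levels[i];
    while (!q.empty()) {
      int c = q.front(); q.pop();
      int x = c % nx, y = (c / nx) % ny, z = c / (nx * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
              continue;
            R_xlen_t j = xx + nx * (yy + (R_xlen_t)ny * zz);
            if (levels[j] == lev && lab[j] == 0) { lab[j] = next; q.push((int)j); }
          }
    }
  }
  return lab;
}

// NGTDM accumulators: per level i, n_i (count of valid voxels) and
// s_i (summed |level - mean of 26-neighborhood in-mask levels|).
// Voxels without any in-mask neighbor do not contribute.
// [[Rcpp::export]]
NumericMatrix cpp_ngtdm(IntegerVector levels, IntegerVector dim, int nlev) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix out(nlev, 2);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int a = at(levels, x, y, z, nx, ny, nz);
        if (a <= 0) continue;
        double sum = 0; int cnt = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              int b = at(levels, x + dx, y + dy, z + dz, nx, ny, nz);
              if (b > 0) { sum += b; ++cnt; }
            }
        if (cnt == 0) continue;
        out(a - 1, 0) += 1.0;
        out(a - 1, 1) += std::abs((double)a - sum / cnt);
      }
  return out;
}

// 26-connected components of a binary mask (for segmentation post-processing).
// [[Rcpp::export]]
IntegerVector cpp_label_mask(LogicalVector mask, IntegerVector dim) {
  R_xlen_t n = mask.size();
  IntegerVector lv(n);
  for (R_xlen_t i = 0; i < n; ++i) lv[i] = mask[i] ? 1 : 0;
  return cpp_label_zones(lv, dim);
}
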