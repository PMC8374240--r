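#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 13 unique 3D direction offsets (one per axis of the 26-neighbourhood,
// signs folded: the opposite offset gives the same matrix after symmetrisation)
static const int DIRS[13][3] = {
  {1, 0, 0}, {0, 1, 0}, {0, 0, 1},
  {1, 1, 0}, {1, -1, 0}, {1, 0, 1}, {1, 0, -1},
  {0, 1, 1}, {0, 1, -1},
  {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {1, -1, -1}
};

static inline int vidx(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

static inline bool inside(int x, int y, int z, int nx, int ny, int nz) {
  return x >= 0 && x < nx && y >= 0 && y < ny && z >= 0 && z < nz;
}

// Symmetric gray-level co-occurrence counts at distance 1.
// levels: flattened 3D integer array, 0 outside ROI, 1..ng inside.
// Returns ng x ng x 13 array of counts (each unordered pair counted twice).
// [[Rcpp::export]]
NumericVector cpp_glcm(IntegerVector levels, IntegerVector dim, int ng) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out(ng * ng * 13);
  for (int d = 0; d < 13; ++d) {
    int dx = DIRS[d][0], dy = DIRS[d][1], dz = DIRS[d][2];
    double *m = &out[d * ng * ng];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int la = levels[vidx(x, y, z, nx, ny)];
          if (la == 0) continue;
          int x2 = x + dx, y2 = y + dy, z2 = z + dz;
          if (!inside(x2, y2, z2, nx, ny, nz)) continue;
          int lb = levels[vidx(x2, y2, z2, nx, ny)];
          if (lb == 0) continue;
          m[(la - 1) + ng * (lb - 1)] += 1.0;
          m[(lb - 1) + ng * (la - 1)] += 1.0;
        }
  }
  out.attr("dim") = IntegerVector::create(ng, ng, 13);
  return out;
}

// Gray-level run length counts per direction: ng x maxlen x 13.
// Runs are maximal sequences of equal level along a direction; out-of-ROI
// voxels break runs.
// [[Rcpp::export]]
NumericVector cpp_glrlm(IntegerVector levels, IntegerVector dim, int ng) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int lmax = std::max(nx, std::max(ny, nz));
  NumericVector out(ng * lmax * 13);
  for (int d = 0; d < 13; ++d) {
    int dx = DIRS[d][0], dy = DIRS[d][1], dz = DIRS[d][2];
    double *m = &out[d * ng * lmax];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          // start of a line: no predecessor within the grid
          if (inside(x - dx, y - dy, z - dz, nx, ny, nz)) continue;
          int cx = x, cy = y, cz = z;
          int cur = 0, len = 0;
          while (inside(cx, cy, cz, nx, ny, nz)) {
            int l = levels[vidx(cx, cy, cz, nx, ny)];
            if (l == cur && l != 0) {
              ++len;
            } else {
              if (cur != 0) m[(cur - 1) + ng * (len - 1)] += 1.0;
              cur = l;
              len = (l != 0) ? 1 : 0;
            }
            cx += dx; cy += dy; cz += dz;
          }
          if (cur != 0) m[(cur - 1) + ng * (len - 1)] += 1.0;
        }
  }
  out.attr("dim") = IntegerVector::create(ng, lmax, 13);
  return out;
}

// Size zones: 26-connected components of equal level within the ROI.
// Returns a 2-column matrix (level, size), one row per zone.
// [[Rcpp::export]]
IntegerMatrix cpp_glszm(IntegerVector levels, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = nx * ny * nz;
  std::vector<char> seen(n, 0);
  std::vector<int> zl, zs, stack;
  for (int z0 = 0; z0 < nz; ++z0)
    for (int y0 = 0; y0 < ny; ++y0)
      for (int x0 = 0; x0 < nx; ++x0) {
        int i0 = vidx(x0, y0, z0, nx, ny);
        if (seen[i0] || levels[i0] == 0) continue;
        int lev = levels[i0], size = 0;
        stack.clear();
        stack.push_back(i0);
        seen[i0] = 1;
        while (!stack.empty()) {
          int i = stack.back();
          stack.pop_back();
          ++size;
          int x = i % nx, y = (i / nx) % ny, zz = i / (nx * ny);
          for (int dz = -1; dz <= 1; ++dz)
            for (int dy = -1; dy <= 1; ++dy)
              for (int dx = -1; dx <= 1; ++dx) {
                if (dx == 0 && dy == 0 && dz == 0) continue;
                int x2 = x + dx, y2 = y + dy, z2 = zz + dz;
                if (!inside(x2, y2, z2, nx, ny, nz)) continue;
                int j = vidx(x2, y2, z2, nx, ny);
                if (!seen[j] && levels[j] == lev) {
                  seen[j] = 1;
                  stack.push_back(j);
                }
              }
        }
        zl.push_back(lev);
        zs.push_back(size);
      }
  IntegerMatrix out(zl.size(), 2);
  for (size_t k = 0; k < zl.size(); ++k) {
    out(k, 0) = zl[k];
    out(k, 1) = zs[k];
  }
  return out;
}

// Neighbouring gray tone difference: per level i, n_i (voxel count) and
// s_i = sum over those voxels of |level - mean(valid 26-neighbour levels)|.
// Voxels with no in-ROI neighbour contribute to n_i with difference 0.
// [[Rcpp::export]]
NumericMatrix cpp_ngtdm(IntegerVector levels, IntegerVector dim, int ng) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix out(ng, 2);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int l = levels[vidx(x, y, z, nx, ny)];
        if (l == 0) continue;
        double sum = 0.0;
        int cnt = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              int x2 = x + dx, y2 = y + dy, z2 = z + dz;
              if (!inside(x2, y2, z2, nx, ny, nz)) continue;
              int l2 = levels[vidx(x2, y2, z2, nx, ny)];
              if (l2 != 0) { sum += l2; ++cnt; }
            }
        out(l - 1, 0) += 1.0;
        if (cnt > 0) out(l - 1, 1) += std::fabs(l - sum / cnt);
      }
  return out;
}

// Gray-level dependence counts: dependence of a voxel = 1 + number of in-ROI
// 26-neighbours whose level differs by <= alpha. Returns ng x 27 counts,
// column j = dependence j.
// [[Rcpp::export]]
NumericMatrix cpp_gldm(IntegerVector levels, IntegerVector dim, int ng,
                       int alpha) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix out(ng, 27);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int l = levels[vidx(x, y, z, nx, ny)];
        if (l == 0) continue;
        int dep = 1;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              int x2 = x + dx, y2 = y + dy, z2 = z + dz;
              if (!inside(x2, y2, z2, nx, ny, nz)) continue;
              int l2 = levels[vidx(x2, y2, z2, nx, ny)];
              if (l2 != 0 && std::abs(l2 - l) <= alpha) ++dep;
            }
        out(l - 1, dep - 1) += 1.0;
      }
  return out;
}
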