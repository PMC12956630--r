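#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// The 13 unique 3D unit offsets (half of the 26-neighborhood).
static const int OFF13[13][3] = {
  {1,0,0},{0,1,0},{0,0,1},
  {1,1,0},{1,-1,0},{1,0,1},{1,0,-1},{0,1,1},{0,1,-1},
  {1,1,1},{1,1,-1},{1,-1,1},{1,-1,-1}
};

static inline int lin(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

static inline double log2d(double x) { return std::log(x) / std::log(2.0); }

// Symmetric co-occurrence counts per offset on a region-coded grid
// (level 0 = outside region). Returns an (Ng*Ng) x 13 matrix of counts.
// [[Rcpp::export]]
NumericMatrix cpp_glcm(IntegerVector grid, IntegerVector dim, int ng) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix out(ng * ng, 13);
  for (int o = 0; o < 13; ++o) {
    int dx = OFF13[o][0], dy = OFF13[o][1], dz = OFF13[o][2];
    for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      int g1 = grid[lin(x, y, z, nx, ny)];
      if (g1 == 0) continue;
      int xo = x + dx, yo = y + dy, zo = z + dz;
      if (xo < 0 || xo >= nx || yo < 0 || yo >= ny || zo < 0 || zo >= nz)
        continue;
      int g2 = grid[lin(xo, yo, zo, nx, ny)];
      if (g2 == 0) continue;
      out((g1 - 1) * ng + (g2 - 1), o) += 1.0;
      out((g2 - 1) * ng + (g1 - 1), o) += 1.0;
    }
  }
  return out;
}

// Run-length counts per direction: maximal same-level runs, truncated at
// the region boundary. Returns an (Ng * maxlen) x 13 matrix; row index is
// (level-1)*maxlen + (runlen-1).
// [[Rcpp::export]]
NumericMatrix cpp_glrlm(IntegerVector grid, IntegerVector dim, int ng,
                        int maxlen) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix out(ng * maxlen, 13);
  for (int o = 0; o < 13; ++o) {
    int dx = OFF13[o][0], dy = OFF13[o][1], dz = OFF13[o][2];
    for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      int g = grid[lin(x, y, z, nx, ny)];
      if (g == 0) continue;
      // run start: predecessor along -d is outside volume/region or differs
      int xp = x - dx, yp = y - dy, zp = z - dz;
      if (xp >= 0 && xp < nx && yp >= 0 && yp < ny && zp >= 0 && zp < nz &&
          grid[lin(xp, yp, zp, nx, ny)] == g)
        continue;
      int len = 1;
      int xn = x + dx, yn = y + dy, zn = z + dz;
      while (xn >= 0 && xn < nx && yn >= 0 && yn < ny && zn >= 0 && zn < nz &&
             grid[lin(xn, yn, zn, nx, ny)] == g) {
        ++len; xn += dx; yn += dy; zn += dz;
      }
      if (len > maxlen) len = maxlen;
      out((g - 1) * maxlen + (len - 1), o) += 1.0;
    }
  }
  return out;
}

// 26-connected equal-level zones. Returns a matrix with one row per zone:
// (level, size).
// [[Rcpp::export]]
IntegerMatrix cpp_glszm_zones(IntegerVector grid, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = nx * ny * nz;
  std::vector<int> lab(n, 0);
  std::vector<int> zl, zs;
  std::vector<int> stack;
  int nzone = 0;
  for (int v = 0; v < n; ++v) {
    if (grid[v] == 0 || lab[v] != 0) continue;
    int level = grid[v];
    ++nzone;
    int size = 0;
    stack.clear();
    stack.push_back(v);
    lab[v] = nzone;
    while (!stack.empty()) {
      int u = stack.back(); stack.pop_back();
      ++size;
      int ux = u % nx, uy = (u / nx) % ny, uz = u / (nx * ny);
      for (int dz = -1; dz <= 1; ++dz) for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (!dx && !dy && !dz) continue;
        int xo = ux + dx, yo = uy + dy, zo = uz + dz;
        if (xo < 0 || xo >= nx || yo < 0 || yo >= ny || zo < 0 || zo >= nz)
          continue;
        int w = lin(xo, yo, zo, nx, ny);
        if (grid[w] == level && lab[w] == 0) {
          lab[w] = nzone;
          stack.push_back(w);
        }
      }
    }
    zl.push_back(level);
    zs.push_back(size);
  }
  IntegerMatrix out(nzone, 2);
  for (int i = 0; i < nzone; ++i) { out(i, 0) = zl[i]; out(i, 1) = zs[i]; }
  return out;
}

// NGTDM accumulators: per level i, n_i = count of region voxels of level i
// with at least one in-region 26-neighbor, s_i = sum over those voxels of
// |i - mean(in-region 26-neighbor levels)|. Returns Ng x 2 (n_i, s_i).
// [[Rcpp::export]]
NumericMatrix cpp_ngtdm(IntegerVector grid, IntegerVector dim, int ng) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix out(ng, 2);
  for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y)
  for (int x = 0; x < nx; ++x) {
    int g = grid[lin(x, y, z, nx, ny)];
    if (g == 0) continue;
    double s = 0.0; int cnt = 0;
    for (int dz = -1; dz <= 1; ++dz) for (int dy = -1; dy <= 1; ++dy)
    for (int dx = -1; dx <= 1; ++dx) {
      if (!dx && !dy && !dz) continue;
      int xo = x + dx, yo = y + dy, zo = z + dz;
      if (xo < 0 || xo >= nx || yo < 0 || yo >= ny || zo < 0 || zo >= nz)
        continue;
      int g2 = grid[lin(xo, yo, zo, nx, ny)];
      if (g2 == 0) continue;
      s += g2; ++cnt;
    }
    if (cnt > 0) {
      out(g - 1, 0) += 1.0;
      out(g - 1, 1) += std::fabs(g - s / cnt);
    }
  }
  return out;
}

// GLDM counts: dependence of a voxel = number of in-region 26-neighbors
// whose level differs by at most alpha. Returns Ng x 27 counts over
// (level, dependence 0..26).
// [[Rcpp::export]]
NumericMatrix cpp_gldm(IntegerVector grid, IntegerVector dim, int ng,
                       int alpha) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix out(ng, 27);
  for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y)
  for (int x = 0; x < nx; ++x) {
    int g = grid[lin(x, y, z, nx, ny)];
    if (g == 0) continue;
    int dep = 0;
    for (int dz = -1; dz <= 1; ++dz) for (int dy = -1; dy <= 1; ++dy)
    for (int dx = -1; dx <= 1; ++dx) {
      if (!dx && !dy && !dz) continue;
      int xo = x + dx, yo = y + dy, zo = z + dz;
      if (xo < 0 || xo >= nx || yo < 0 || yo >= ny || zo < 0 || zo >= nz)
        continue;
      int g2 = grid[lin(xo, yo, zo, nx, ny)];
      if (g2 == 0) continue;
      if (std::abs(g2 - g) <= alpha) ++dep;
    }
    out(g - 1, dep) += 1.0;
  }
  return out;
}
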