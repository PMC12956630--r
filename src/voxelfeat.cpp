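#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Sliding-window engine for voxel-local texture features.
//
// For every in-mask voxel the window is the cubic neighborhood of radius r,
// clipped to the volume and restricted to in-mask voxels. Maintained
// incrementally along x for each (y, z) row:
//   - gray-level histogram (first-order entropy),
//   - symmetric co-occurrence counts over the 26 unit directions
//     (joint energy / joint entropy / difference entropy),
//   - level moments and summed gray-tone differences (NGTDM contrast,
//     with each voxel's gray-tone difference precomputed against its own
//     in-mask 26-neighborhood).
// Entropies use H = log2(total) - sum(c*log2(c))/total, updated in O(1)
// per count change through a precomputed x*log2(x) table.

static const int DIR26[26][3] = {
  {1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1},
  {1,1,0},{-1,-1,0},{1,-1,0},{-1,1,0},
  {1,0,1},{-1,0,-1},{1,0,-1},{-1,0,1},
  {0,1,1},{0,-1,-1},{0,1,-1},{0,-1,1},
  {1,1,1},{-1,-1,-1},{1,1,-1},{-1,-1,1},
  {1,-1,1},{-1,1,-1},{1,-1,-1},{-1,1,1}
};

struct WinState {
  int nbins;
  std::vector<int> hist;     // per-level in-window counts
  std::vector<int> glcm;     // symmetric pair counts, nbins x nbins
  std::vector<int> dcount;   // |i-j| marginal counts
  double S_h, S_g, S_d;      // sum c*log2(c) accumulators
  long long P, Q;            // total pair count, sum of squared cell counts
  int n, npresent;
  double m1, m2, sdelta;
  const std::vector<double>* xlog;

  void reset() {
    std::fill(hist.begin(), hist.end(), 0);
    std::fill(glcm.begin(), glcm.end(), 0);
    std::fill(dcount.begin(), dcount.end(), 0);
    S_h = S_g = S_d = 0.0; P = Q = 0; n = npresent = 0;
    m1 = m2 = sdelta = 0.0;
  }

  inline double xl(int c) const { return (*xlog)[c]; }

  inline void cell_add(int i, int j, int amt) {
    int &c = glcm[i * nbins + j];
    S_g += xl(c + amt) - xl(c);
    Q += (long long)(c + amt) * (c + amt) - (long long)c * c;
    c += amt;
  }

  inline void pair_add(int i, int j) { // one symmetric co-occurring pair
    if (i == j) {
      cell_add(i, i, 2);
    } else {
      cell_add(i, j, 1);
      cell_add(j, i, 1);
    }
    int &d = dcount[std::abs(i - j)];
    S_d += xl(d + 2) - xl(d);
    d += 2;
    P += 2;
  }

  inline void pair_remove(int i, int j) {
    if (i == j) {
      cell_add(i, i, -2);
    } else {
      cell_add(i, j, -1);
      cell_add(j, i, -1);
    }
    int &d = dcount[std::abs(i - j)];
    S_d += xl(d - 2) - xl(d);
    d -= 2;
    P -= 2;
  }

  inline void hist_add(int g, double delta) {
    int &c = hist[g];
    S_h += xl(c + 1) - xl(c);
    if (c == 0) ++npresent;
    ++c; ++n;
    m1 += g + 1; m2 += (double)(g + 1) * (g + 1); sdelta += delta;
  }

  inline void hist_remove(int g, double delta) {
    int &c = hist[g];
    S_h += xl(c - 1) - xl(c);
    --c; --n;
    if (c == 0) --npresent;
    m1 -= g + 1; m2 -= (double)(g + 1) * (g + 1); sdelta -= delta;
  }
};

// `compute` marks the voxels whose features are emitted (subset of the
// mask); neighborhoods always use the full mask, so emitted values are
// identical to a full run restricted to those voxels. Rows without any
// compute voxel are skipped entirely.
// [[Rcpp::export]]
NumericMatrix cpp_voxel_features(IntegerVector binned, LogicalVector mask,
                                 LogicalVector compute, IntegerVector dim,
                                 int radius, int nbins) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int r = radius;
  const long long N = (long long)nx * ny * nz;

  // gray-tone difference of each in-mask voxel vs its in-mask 26-neighbors
  std::vector<double> delta((size_t)N, 0.0);
  for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y)
  for (int x = 0; x < nx; ++x) {
    long long v = x + (long long)nx * (y + (long long)ny * z);
    if (!mask[v]) continue;
    double s = 0.0; int cnt = 0;
    for (int d = 0; d < 26; ++d) {
      int xo = x + DIR26[d][0], yo = y + DIR26[d][1], zo = z + DIR26[d][2];
      if (xo < 0 || xo >= nx || yo < 0 || yo >= ny || zo < 0 || zo >= nz)
        continue;
      long long w = xo + (long long)nx * (yo + (long long)ny * zo);
      if (!mask[w]) continue;
      s += binned[w]; ++cnt;
    }
    if (cnt > 0) delta[v] = std::fabs(binned[v] - s / cnt);
  }

  // x*log2(x) table sized for the largest possible count in any accumulator
  int wmax = (2 * r + 1) * (2 * r + 1) * (2 * r + 1);
  int cap = 26 * wmax + 4;
  std::vector<double> xlog(cap, 0.0);
  for (int c = 1; c < cap; ++c) xlog[c] = c * std::log2((double)c);

  WinState st;
  st.nbins = nbins;
  st.hist.assign(nbins, 0);
  st.glcm.assign((size_t)nbins * nbins, 0);
  st.dcount.assign(nbins, 0);
  st.xlog = &xlog;

  std::vector<char> inwin((size_t)N, 0);

  int nvox = 0;
  for (long long v = 0; v < N; ++v) if (compute[v]) ++nvox;
  NumericMatrix out(nvox, 5);
  std::vector<int> rowof((size_t)N, -1);
  {
    int row = 0;
    for (long long v = 0; v < N; ++v) if (compute[v]) rowof[v] = row++;
  }

  std::vector<long long> added; added.reserve((size_t)wmax);

  for (int z = 0; z < nz; ++z) {
    int z0 = std::max(0, z - r), z1 = std::min(nz - 1, z + r);
    for (int y = 0; y < ny; ++y) {
      int y0 = std::max(0, y - r), y1 = std::min(ny - 1, y + r);
      // does this row contain any voxel to compute?
      bool any = false;
      for (int x = 0; x < nx; ++x) {
        long long v = x + (long long)nx * (y + (long long)ny * z);
        if (compute[v]) { any = true; break; }
      }
      if (!any) continue;

      st.reset();
      added.clear();

      auto add_plane = [&](int px) {
        if (px < 0 || px >= nx) return;
        for (int zz = z0; zz <= z1; ++zz) for (int yy = y0; yy <= y1; ++yy) {
          long long v = px + (long long)nx * (yy + (long long)ny * zz);
          if (!mask[v]) continue;
          int g = binned[v] - 1;
          st.hist_add(g, delta[v]);
          inwin[v] = 1;
          added.push_back(v);
          int vx = px, vy = yy, vz = zz;
          for (int d = 0; d < 26; ++d) {
            int xo = vx + DIR26[d][0], yo = vy + DIR26[d][1],
                zo = vz + DIR26[d][2];
            if (xo < 0 || xo >= nx || yo < y0 || yo > y1 || zo < z0 ||
                zo > z1)
              continue;
            long long w = xo + (long long)nx * (yo + (long long)ny * zo);
            if (!inwin[w] || w == v) continue;
            int g2 = binned[w] - 1;
            if (d % 2 == 0) st.pair_add(g, g2); else st.pair_add(g2, g);
          }
        }
      };
      auto remove_plane = [&](int px) {
        if (px < 0 || px >= nx) return;
        for (int zz = z0; zz <= z1; ++zz) for (int yy = y0; yy <= y1; ++yy) {
          long long v = px + (long long)nx * (yy + (long long)ny * zz);
          if (!mask[v] || !inwin[v]) continue;
          inwin[v] = 0;
          int g = binned[v] - 1;
          int vx = px, vy = yy, vz = zz;
          for (int d = 0; d < 26; ++d) {
            int xo = vx + DIR26[d][0], yo = vy + DIR26[d][1],
                zo = vz + DIR26[d][2];
            if (xo < 0 || xo >= nx || yo < y0 || yo > y1 || zo < z0 ||
                zo > z1)
              continue;
            long long w = xo + (long long)nx * (yo + (long long)ny * zo);
            if (!inwin[w]) continue;
            int g2 = binned[w] - 1;
            if (d % 2 == 0) st.pair_remove(g, g2); else st.pair_remove(g2, g);
          }
          st.hist_remove(g, delta[v]);
        }
      };

      for (int px = 0; px <= std::min(r, nx - 1); ++px) add_plane(px);

      for (int x = 0; x < nx; ++x) {
        if (x > 0) {
          add_plane(x + r);
          remove_plane(x - r - 1);
        }
        long long v = x + (long long)nx * (y + (long long)ny * z);
        if (!compute[v]) continue;

        double fo = 0.0, je = 1.0, hj = 0.0, hd = 0.0, contrast = 0.0;
        if (st.npresent > 1) { // single-level windows are exactly degenerate
          if (st.n > 0) fo = std::log2((double)st.n) - st.S_h / st.n;
          if (st.P > 0) {
            double Pd = (double)st.P;
            je = (double)st.Q / (Pd * Pd);
            hj = std::log2(Pd) - st.S_g / Pd;
            hd = std::log2(Pd) - st.S_d / Pd;
          }
        }
        if (st.npresent > 1 && st.n > 0) {
          double nn = (double)st.n;
          double c1 = 2.0 * (nn * st.m2 - st.m1 * st.m1) / (nn * nn);
          contrast = c1 / ((double)st.npresent * (st.npresent - 1)) *
            (st.sdelta / nn);
        }
        int row = rowof[v];
        out(row, 0) = fo;
        out(row, 1) = hd;
        out(row, 2) = je;
        out(row, 3) = hj;
        out(row, 4) = contrast;
      }

      // clear window flags for the next row
      for (size_t i = 0; i < added.size(); ++i) inwin[added[i]] = 0;
    }
  }
  return out;
}

// Separable Gaussian smoothing with replicate (clamped) boundary handling;
// sigma per axis in voxels. Small sigmas use the exact truncated kernel
// (3 sigma); large ones use three running-sum box passes whose combined
// variance matches sigma^2 — the standard O(1)-per-voxel approximation,
// ample for generating smooth random fields.
static void blur_line(std::vector<double> &cur, std::vector<double> &nxt,
                      long long base, int len, long long stride,
                      const std::vector<double> &k, int half) {
  for (int i = 0; i < len; ++i) {
    double acc = 0.0;
    for (int j = -half; j <= half; ++j) {
      int ii = std::min(len - 1, std::max(0, i + j));
      acc += k[j + half] * cur[base + ii * stride];
    }
    nxt[base + i * stride] = acc;
  }
}

static void box_line(std::vector<double> &cur, std::vector<double> &nxt,
                     long long base, int len, long long stride, int rb) {
  // normalized box mean of radius rb with clamped edges via prefix sums
  std::vector<double> ps(len + 1, 0.0);
  for (int i = 0; i < len; ++i) ps[i + 1] = ps[i] + cur[base + i * stride];
  for (int i = 0; i < len; ++i) {
    int lo = std::max(0, i - rb), hi = std::min(len - 1, i + rb);
    nxt[base + i * stride] = (ps[hi + 1] - ps[lo]) / (hi - lo + 1);
  }
}

// [[Rcpp::export]]
NumericVector cpp_smooth3d(NumericVector a, IntegerVector dim,
                           NumericVector sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const long long N = (long long)nx * ny * nz;
  std::vector<double> cur(a.begin(), a.end()), nxt((size_t)N);

  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 1e-8) continue;
    int half = std::max(1, (int)std::ceil(3 * s));
    bool use_box = half > 8;
    std::vector<double> k;
    int rb = 0;
    if (use_box) {
      rb = std::max(1, (int)std::lround((std::sqrt(4 * s * s + 1) - 1) / 2));
    } else {
      k.resize(2 * half + 1);
      double tot = 0.0;
      for (int i = -half; i <= half; ++i) {
        k[i + half] = std::exp(-0.5 * i * i / (s * s));
        tot += k[i + half];
      }
      for (double &v : k) v /= tot;
    }

    int len = ax == 0 ? nx : (ax == 1 ? ny : nz);
    long long stride = ax == 0 ? 1 : (ax == 1 ? nx : (long long)nx * ny);
    int npass = use_box ? 3 : 1;
    for (int pass = 0; pass < npass; ++pass) {
      for (int z = 0; z < (ax == 2 ? 1 : nz); ++z)
      for (int y = 0; y < (ax == 1 ? 1 : ny); ++y)
      for (int x = 0; x < (ax == 0 ? 1 : nx); ++x) {
        long long base;
        if (ax == 0) base = (long long)nx * (y + (long long)ny * z);
        else if (ax == 1) base = x + (long long)nx * ny * z;
        else base = x + (long long)nx * y;
        if (use_box) box_line(cur, nxt, base, len, stride, rb);
        else blur_line(cur, nxt, base, len, stride, k, half);
      }
      std::swap(cur, nxt);
    }
  }
  return NumericVector(cur.begin(), cur.end());
}
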