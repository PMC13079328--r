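#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Linear index helpers for column-major (R) 3D arrays, 0-based.
static inline int lin(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// Neighbor offset tables for 6/18/26 connectivity.
static void neighbor_offsets(int connectivity,
                             std::vector<int>& dx,
                             std::vector<int>& dy,
                             std::vector<int>& dz) {
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        int n = std::abs(a) + std::abs(b) + std::abs(c);
        if (n == 0) continue;
        bool keep = (connectivity == 26) ||
                    (connectivity == 18 && n <= 2) ||
                    (connectivity == 6 && n == 1);
        if (keep) { dx.push_back(a); dy.push_back(b); dz.push_back(c); }
      }
}

// [[Rcpp::export(name = ".cc_label3d")]]
IntegerVector cc_label3d(IntegerVector mask, IntegerVector dims,
                         int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  std::vector<int> dx, dy, dz;
  neighbor_offsets(connectivity, dx, dy, dz);
  const int nn = (int)dx.size();

  IntegerVector lab(n, 0);
  int next = 0;
  std::vector<int> stack;
  // scan in column-major order so labels are deterministic:
  // component k is the k-th distinct component met in array order
  for (int i = 0; i < n; ++i) {
    if (mask[i] == 0 || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      int cz = cur / (nx * ny);
      int rem = cur - cz * nx * ny;
      int cy = rem / nx;
      int cx = rem - cy * nx;
      for (int k = 0; k < nn; ++k) {
        int x = cx + dx[k], y = cy + dy[k], z = cz + dz[k];
        if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz)
          continue;
        int j = lin(x, y, z, nx, ny);
        if (mask[j] != 0 && lab[j] == 0) {
          lab[j] = next;
          stack.push_back(j);
        }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}

// Erosion with the 6-connected cross structuring element; voxels outside
// the array are background, so border voxels never survive.
// [[Rcpp::export(name = ".erode_cross3d")]]
IntegerVector erode_cross3d(IntegerVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  IntegerVector out(n, 0);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int i = lin(x, y, z, nx, ny);
        if (mask[i] == 0) continue;
        if (x == 0 || y == 0 || z == 0 ||
            x == nx - 1 || y == ny - 1 || z == nz - 1) continue;
        if (mask[i - 1] && mask[i + 1] &&
            mask[i - nx] && mask[i + nx] &&
            mask[i - nx * ny] && mask[i + nx * ny])
          out[i] = 1;
      }
  return out;
}

// 1D squared-distance transform (Felzenszwalb & Huttenlocher) on a
// sampled line with grid step `step` (mm). Positions with infinite f
// (no source anywhere on that row yet) are skipped as parabola
// vertices; the caller skips rows that are entirely infinite.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 int n, double step,
                 std::vector<int>& v, std::vector<double>& zb) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;
    double qq = (double)q * step;
    if (k < 0) {
      k = 0;
      v[0] = q;
      zb[0] = -INF;
      zb[1] = INF;
      continue;
    }
    double s;
    while (true) {
      double vv = (double)v[k] * step;
      s = ((f[q] + qq * qq) - (f[v[k]] + vv * vv)) / (2.0 * qq - 2.0 * vv);
      if (s <= zb[k] && k > 0) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zb[k] = s;
    zb[k + 1] = INF;
  }
  if (k < 0) {  // no finite vertex on this row
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    double qq = (double)q * step;
    while (zb[j + 1] < qq) ++j;
    double vv = (double)v[j] * step;
    d[q] = (qq - vv) * (qq - vv) + f[v[j]];
  }
}

// Exact Euclidean distance transform: distance (mm) from each voxel
// center to the nearest foreground voxel center, anisotropic spacing.
// [[Rcpp::export(name = ".edt3d")]]
NumericVector edt3d(IntegerVector mask, IntegerVector dims,
                    NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> d(n);
  for (int i = 0; i < n; ++i) d[i] = mask[i] ? 0.0 : INF;

  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), g(nmax);
  std::vector<int> v(nmax);
  std::vector<double> zb(nmax + 1);
  // pass along x
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      bool any = false;
      for (int x = 0; x < nx; ++x) {
        f[x] = d[lin(x, y, z, nx, ny)];
        if (f[x] < INF) any = true;
      }
      if (!any) continue;  // stays INF
      dt1d(f, g, nx, spacing[0], v, zb);
      for (int x = 0; x < nx; ++x) d[lin(x, y, z, nx, ny)] = g[x];
    }
  // pass along y
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      bool any = false;
      for (int y = 0; y < ny; ++y) {
        f[y] = d[lin(x, y, z, nx, ny)];
        if (f[y] < INF) any = true;
      }
      if (!any) continue;
      dt1d(f, g, ny, spacing[1], v, zb);
      for (int y = 0; y < ny; ++y) d[lin(x, y, z, nx, ny)] = g[y];
    }
  // pass along z
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      bool any = false;
      for (int z = 0; z < nz; ++z) {
        f[z] = d[lin(x, y, z, nx, ny)];
        if (f[z] < INF) any = true;
      }
      if (!any) continue;
      dt1d(f, g, nz, spacing[2], v, zb);
      for (int z = 0; z < nz; ++z) d[lin(x, y, z, nx, ny)] = g[z];
    }
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = std::sqrt(d[i]);
  return out;
}

// Minimum Euclidean distance (mm) from an arbitrary point to the nearest
// foreground voxel center, by an expanding cubic (Chebyshev) window.
// The window keeps growing after the first hit until no voxel outside it
// can beat the current best: every voxel outside a window of radius r
// around the point's nearest voxel index is at least (r + 0.5) * min
// spacing away from the point along some axis.
// [[Rcpp::export(name = ".min_dist_expand")]]
double min_dist_expand(NumericVector point_mm, IntegerVector mask,
                       IntegerVector dims, NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double px = point_mm[0], py = point_mm[1], pz = point_mm[2];
  const double min_sp = std::min(sx, std::min(sy, sz));

  int cx = (int)std::lround(px / sx);
  int cy = (int)std::lround(py / sy);
  int cz = (int)std::lround(pz / sz);
  cx = std::min(std::max(cx, 0), nx - 1);
  cy = std::min(std::max(cy, 0), ny - 1);
  cz = std::min(std::max(cz, 0), nz - 1);

  const double INF = std::numeric_limits<double>::infinity();
  double best = INF;
  int rmax = std::max(std::max(cx, nx - 1 - cx),
             std::max(std::max(cy, ny - 1 - cy),
                      std::max(cz, nz - 1 - cz)));
  for (int r = 0; r <= rmax; ++r) {
    // scan the Chebyshev shell at radius exactly r
    int x0 = std::max(cx - r, 0), x1 = std::min(cx + r, nx - 1);
    int y0 = std::max(cy - r, 0), y1 = std::min(cy + r, ny - 1);
    int z0 = std::max(cz - r, 0), z1 = std::min(cz + r, nz - 1);
    for (int z = z0; z <= z1; ++z)
      for (int y = y0; y <= y1; ++y) {
        bool face = (z == cz - r || z == cz + r ||
                     y == cy - r || y == cy + r);
        if (face) {
          for (int x = x0; x <= x1; ++x) {
            if (mask[lin(x, y, z, nx, ny)] == 0) continue;
            double ddx = x * sx - px, ddy = y * sy - py, ddz = z * sz - pz;
            double dd = std::sqrt(ddx * ddx + ddy * ddy + ddz * ddz);
            if (dd < best) best = dd;
          }
        } else {
          const int xcand[2] = {cx - r, cx + r};
          int nc = (r == 0) ? 1 : 2;
          for (int k = 0; k < nc; ++k) {
            int x = xcand[k];
            if (x < 0 || x >= nx) continue;
            if (mask[lin(x, y, z, nx, ny)] == 0) continue;
            double ddx = x * sx - px, ddy = y * sy - py, ddz = z * sz - pz;
            double dd = std::sqrt(ddx * ddx + ddy * ddy + ddz * ddz);
            if (dd < best) best = dd;
          }
        }
      }
    if (best <= ((double)r + 0.5) * min_sp) break;
  }
  if (best == INF) return R_PosInf;  // empty mask
  return best;
}

// Stochastic region growing: starting from seed voxels, repeatedly add a
// random subset of 6-neighbors inside `allowed` until `target` voxels are
// labeled (or the allowed region is exhausted). Uses R's RNG so results
// are reproducible under set.seed().
// [[Rcpp::export(name = ".grow_region3d")]]
IntegerVector grow_region3d(IntegerVector seeds, IntegerVector allowed,
                            IntegerVector dims, int target,
                            double accept_prob) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  IntegerVector out(n, 0);
  std::vector<int> frontier;
  int count = 0;
  for (int k = 0; k < seeds.size(); ++k) {
    int i = seeds[k];
    if (i < 0 || i >= n || !allowed[i] || out[i]) continue;
    out[i] = 1;
    ++count;
    frontier.push_back(i);
  }
  const int offs[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
  while (count < target && !frontier.empty()) {
    std::vector<int> next;
    bool grew = false;
    for (size_t k = 0; k < frontier.size() && count < target; ++k) {
      int cur = frontier[k];
      int cz = cur / (nx * ny);
      int rem = cur - cz * nx * ny;
      int cy = rem / nx;
      int cx = rem - cy * nx;
      for (int m = 0; m < 6 && count < target; ++m) {
        int x = cx + offs[m][0], y = cy + offs[m][1], z = cz + offs[m][2];
        if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz)
          continue;
        int j = lin(x, y, z, nx, ny);
        if (!allowed[j] || out[j]) continue;
        if (unif_rand() < accept_prob) {
          out[j] = 1;
          ++count;
          next.push_back(j);
          grew = true;
        }
      }
      // keep unexhausted frontier voxels alive so growth can continue
      next.push_back(cur);
    }
    if (!grew && next.size() == frontier.size()) {
      // no neighbor accepted this sweep; retry (RNG advances), but bail
      // out if the frontier is fully enclosed
      bool any_open = false;
      for (size_t k = 0; k < frontier.size() && !any_open; ++k) {
        int cur = frontier[k];
        int cz = cur / (nx * ny);
        int rem = cur - cz * nx * ny;
        int cy = rem / nx;
        int cx = rem - cy * nx;
        for (int m = 0; m < 6; ++m) {
          int x = cx + offs[m][0], y = cy + offs[m][1], z = cz + offs[m][2];
          if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz)
            continue;
          int j = lin(x, y, z, nx, ny);
          if (allowed[j] && !out[j]) { any_open = true; break; }
        }
      }
      if (!any_open) break;
    }
    frontier.swap(next);
  }
  return out;
}
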