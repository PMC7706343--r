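// 3D lattice operations backing the segmentation pipeline: distance
// transforms, connected-component labeling, regional maxima, marker merging
// and marker-based watershed flooding. All arrays are passed as flat vectors
// in R's column-major layout, dim = (nx, ny, nz), x fastest.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// Offsets for 6/18/26 connectivity. 6 = faces, 18 = +edges, 26 = +corners.
static void neighbor_offsets(int connectivity, std::vector<int> &dx,
                             std::vector<int> &dy, std::vector<int> &dz) {
  dx.clear(); dy.clear(); dz.clear();
  for (int k = -1; k <= 1; ++k)
    for (int j = -1; j <= 1; ++j)
      for (int i = -1; i <= 1; ++i) {
        if (i == 0 && j == 0 && k == 0) continue;
        int m = std::abs(i) + std::abs(j) + std::abs(k);
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        dx.push_back(i); dy.push_back(j); dz.push_back(k);
      }
}

// Chessboard (Chebyshev) distance to the nearest background voxel.
// Two-pass chamfer over the 26-neighborhood with unit weights is exact for
// the L-infinity metric on the lattice.
// [[Rcpp::export]]
NumericVector cpp_chessboard_dt(LogicalVector mask, int nx, int ny, int nz) {
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector d(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) d[i] = mask[i] ? INF : 0.0;
  // forward pass: neighbors already visited in (z,y,x ascending) order
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int v = idx3(x, y, z, nx, ny);
        if (d[v] == 0.0) continue;
        double best = d[v];
        for (int k = -1; k <= 0; ++k)
          for (int j = -1; j <= 1; ++j)
            for (int i = -1; i <= 1; ++i) {
              if (k == 0 && (j > 0 || (j == 0 && i >= 0))) continue;
              int xx = x + i, yy = y + j, zz = z + k;
              if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
                continue;
              double cand = d[idx3(xx, yy, zz, nx, ny)] + 1.0;
              if (cand < best) best = cand;
            }
        d[v] = best;
      }
  // backward pass
  for (int z = nz - 1; z >= 0; --z)
    for (int y = ny - 1; y >= 0; --y)
      for (int x = nx - 1; x >= 0; --x) {
        int v = idx3(x, y, z, nx, ny);
        if (d[v] == 0.0) continue;
        double best = d[v];
        for (int k = 0; k <= 1; ++k)
          for (int j = -1; j <= 1; ++j)
            for (int i = -1; i <= 1; ++i) {
              if (k == 0 && (j < 0 || (j == 0 && i <= 0))) continue;
              int xx = x + i, yy = y + j, zz = z + k;
              if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
                continue;
              double cand = d[idx3(xx, yy, zz, nx, ny)] + 1.0;
              if (cand < best) best = cand;
            }
        d[v] = best;
      }
  return d;
}

// One-dimensional squared-distance lower envelope (Felzenszwalb &
// Huttenlocher), applied separably for the exact Euclidean transform.
static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &zb, int n) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  zb[0] = -INF;
  zb[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    if (f[v[0]] == INF) { v[0] = q; zb[1] = INF; continue; }
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= zb[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    zb[k] = s;
    zb[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = (f[v[k]] == INF) ? INF : dq * dq + f[v[k]];
  }
}

// Exact squared Euclidean distance (in voxels) to the nearest background
// voxel; background itself is 0.
// [[Rcpp::export]]
NumericVector cpp_euclidean_dt_sq(LogicalVector mask, int nx, int ny, int nz) {
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector d(mask.size());
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), dd(nmax), zb(nmax + 1);
  std::vector<int> v(nmax);
  // pass along x: 1D distance to nearest zero, then square
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      double run = INF;
      for (int x = 0; x < nx; ++x) {
        int id = idx3(x, y, z, nx, ny);
        run = mask[id] ? ((run == INF) ? INF : run + 1.0) : 0.0;
        d[id] = run;
      }
      run = INF;
      for (int x = nx - 1; x >= 0; --x) {
        int id = idx3(x, y, z, nx, ny);
        run = mask[id] ? ((run == INF) ? INF : run + 1.0) : 0.0;
        if (run < d[id]) d[id] = run;
      }
      for (int x = 0; x < nx; ++x) {
        int id = idx3(x, y, z, nx, ny);
        if (d[id] != INF) d[id] *= d[id];
      }
    }
  // envelope along y, then z
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) f[y] = d[idx3(x, y, z, nx, ny)];
      if (f[std::min_element(f.begin(), f.begin() + ny) - f.begin()] == INF)
        continue;
      dt1d(f, dd, v, zb, ny);
      for (int y = 0; y < ny; ++y) d[idx3(x, y, z, nx, ny)] = dd[y];
    }
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      for (int z = 0; z < nz; ++z) f[z] = d[idx3(x, y, z, nx, ny)];
      if (f[std::min_element(f.begin(), f.begin() + nz) - f.begin()] == INF)
        continue;
      dt1d(f, dd, v, zb, nz);
      for (int z = 0; z < nz; ++z) d[idx3(x, y, z, nx, ny)] = dd[z];
    }
  return d;
}

// Connected-component labeling; labels assigned 1..K in scan order, so the
// result is a pure function of the mask.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, int nx, int ny, int nz,
                          int connectivity) {
  std::vector<int> ox, oy, oz;
  neighbor_offsets(connectivity, ox, oy, oz);
  IntegerVector lab(mask.size(), 0);
  std::vector<int> stack;
  int next = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int v = idx3(x, y, z, nx, ny);
        if (!mask[v] || lab[v]) continue;
        ++next;
        lab[v] = next;
        stack.clear();
        stack.push_back(v);
        while (!stack.empty()) {
          int cur = stack.back();
          stack.pop_back();
          int cz = cur / (nx * ny), rem = cur % (nx * ny);
          int cy = rem / nx, cx = rem % nx;
          for (size_t t = 0; t < ox.size(); ++t) {
            int xx = cx + ox[t], yy = cy + oy[t], zz = cz + oz[t];
            if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
              continue;
            int u = idx3(xx, yy, zz, nx, ny);
            if (mask[u] && !lab[u]) {
              lab[u] = next;
              stack.push_back(u);
            }
          }
        }
      }
  return lab;
}

// Regional maxima of a non-negative map: connected plateaus (26-connectivity
// over equal values, restricted to value > 0) none of whose neighbors is
// strictly higher. Output labels plateaus 1..M in scan order, 0 elsewhere.
// [[Rcpp::export]]
IntegerVector cpp_regional_maxima(NumericVector val, int nx, int ny, int nz) {
  std::vector<int> ox, oy, oz;
  neighbor_offsets(26, ox, oy, oz);
  IntegerVector out(val.size(), 0);
  std::vector<signed char> state(val.size(), 0); // 0 unvisited, 1 visited
  std::vector<int> stack, plateau;
  int next = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int v = idx3(x, y, z, nx, ny);
        if (val[v] <= 0.0 || state[v]) continue;
        double h = val[v];
        bool is_max = true;
        stack.clear(); plateau.clear();
        stack.push_back(v);
        state[v] = 1;
        while (!stack.empty()) {
          int cur = stack.back();
          stack.pop_back();
          plateau.push_back(cur);
          int cz = cur / (nx * ny), rem = cur % (nx * ny);
          int cy = rem / nx, cx = rem % nx;
          for (size_t t = 0; t < ox.size(); ++t) {
            int xx = cx + ox[t], yy = cy + oy[t], zz = cz + oz[t];
            if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
              continue;
            int u = idx3(xx, yy, zz, nx, ny);
            if (val[u] > h) { is_max = false; continue; }
            if (val[u] == h && !state[u]) {
              state[u] = 1;
              stack.push_back(u);
            }
          }
        }
        if (is_max) {
          ++next;
          for (size_t t = 0; t < plateau.size(); ++t) out[plateau[t]] = next;
        }
      }
  return out;
}

struct UnionFind {
  std::vector<int> parent;
  explicit UnionFind(int n) : parent(n) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  }
  void unite(int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  }
};

// Merge labeled regions whose minimum pairwise lattice distance is below
// `threshold` (transitive closure, single linkage). Only regions inside the
// same connected foreground component (`comp`) may merge: maxima in
// distinct objects are never fused, however close the objects lie. metric:
// 0 = chessboard (Chebyshev), 1 = Euclidean. Returns for each input label
// 1..K its merged group id, compacted to 1..M preserving first-appearance
// order.
// `thr_by_comp[c-1]` is the merge threshold used inside component c, so the
// radius scale can differ per object.
// [[Rcpp::export]]
IntegerVector cpp_merge_regions(IntegerVector lab, IntegerVector comp,
                                int nx, int ny, int nz,
                                NumericVector thr_by_comp, int metric) {
  int K = 0;
  for (R_xlen_t i = 0; i < lab.size(); ++i) if (lab[i] > K) K = lab[i];
  if (K == 0) return IntegerVector(0);
  std::vector<std::vector<int> > pts(K); // x,y,z triplets
  std::vector<int> bxmin(K, nx), bymin(K, ny), bzmin(K, nz);
  std::vector<int> bxmax(K, -1), bymax(K, -1), bzmax(K, -1);
  std::vector<int> rcomp(K, 0);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int l = lab[idx3(x, y, z, nx, ny)];
        if (!l) continue;
        int g = l - 1;
        rcomp[g] = comp[idx3(x, y, z, nx, ny)];
        pts[g].push_back(x); pts[g].push_back(y); pts[g].push_back(z);
        bxmin[g] = std::min(bxmin[g], x); bxmax[g] = std::max(bxmax[g], x);
        bymin[g] = std::min(bymin[g], y); bymax[g] = std::max(bymax[g], y);
        bzmin[g] = std::min(bzmin[g], z); bzmax[g] = std::max(bzmax[g], z);
      }
  UnionFind uf(K);
  for (int a = 0; a < K; ++a)
    for (int b = a + 1; b < K; ++b) {
      if (rcomp[a] != rcomp[b]) continue;
      double threshold = thr_by_comp[rcomp[a] - 1];
      if (threshold <= 0) continue;
      // bounding-box separation lower-bounds the point-pair distance
      int gx = std::max(0, std::max(bxmin[a] - bxmax[b], bxmin[b] - bxmax[a]));
      int gy = std::max(0, std::max(bymin[a] - bymax[b], bymin[b] - bymax[a]));
      int gz = std::max(0, std::max(bzmin[a] - bzmax[b], bzmin[b] - bzmax[a]));
      double lb = (metric == 0)
                      ? (double)std::max(gx, std::max(gy, gz))
                      : std::sqrt((double)gx * gx + (double)gy * gy +
                                  (double)gz * gz);
      if (lb >= threshold) continue;
      bool merged = false;
      for (size_t i = 0; i < pts[a].size() && !merged; i += 3)
        for (size_t j = 0; j < pts[b].size() && !merged; j += 3) {
          int ddx = std::abs(pts[a][i] - pts[b][j]);
          int ddy = std::abs(pts[a][i + 1] - pts[b][j + 1]);
          int ddz = std::abs(pts[a][i + 2] - pts[b][j + 2]);
          double dist = (metric == 0)
                            ? (double)std::max(ddx, std::max(ddy, ddz))
                            : std::sqrt((double)ddx * ddx + (double)ddy * ddy +
                                        (double)ddz * ddz);
          if (dist < threshold) {
            uf.unite(a, b);
            merged = true;
          }
        }
    }
  // compact group ids in first-appearance order of the root labels
  std::vector<int> remap(K, 0);
  int M = 0;
  IntegerVector out(K);
  for (int g = 0; g < K; ++g) {
    int r = uf.find(g);
    if (!remap[r]) remap[r] = ++M;
    out[g] = remap[r];
  }
  return out;
}

// Marker-based watershed by priority flooding on the (negated) distance map:
// voxels are claimed in order of decreasing distance starting from the
// markers. Ties resolved by insertion order, so the result is deterministic.
// [[Rcpp::export]]
IntegerVector cpp_watershed(IntegerVector markers, LogicalVector mask,
                            NumericVector dist, int nx, int ny, int nz,
                            int connectivity) {
  std::vector<int> ox, oy, oz;
  neighbor_offsets(connectivity, ox, oy, oz);
  IntegerVector lab(markers.size(), 0);
  typedef std::pair<double, std::pair<int64_t, int> > QE; // (dist, (-order, idx))
  std::priority_queue<QE> pq;
  int64_t order = 0;
  for (R_xlen_t i = 0; i < markers.size(); ++i)
    if (markers[i] > 0 && mask[i]) {
      lab[i] = markers[i];
      pq.push(QE(dist[i], std::make_pair(-(order++), (int)i)));
    }
  while (!pq.empty()) {
    int cur = pq.top().second.second;
    pq.pop();
    int cz = cur / (nx * ny), rem = cur % (nx * ny);
    int cy = rem / nx, cx = rem % nx;
    for (size_t t = 0; t < ox.size(); ++t) {
      int xx = cx + ox[t], yy = cy + oy[t], zz = cz + oz[t];
      if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
        continue;
      int u = idx3(xx, yy, zz, nx, ny);
      if (mask[u] && lab[u] == 0) {
        lab[u] = lab[cur];
        pq.push(QE(dist[u], std::make_pair(-(order++), u)));
      }
    }
  }
  return lab;
}

// Separable Gaussian blur with reflected boundaries; sigma per axis in
// voxels. Used by the phantom generator and iso-surface pre-smoothing.
// [[Rcpp::export]]
NumericVector cpp_gaussian_blur(NumericVector vol, int nx, int ny, int nz,
                                double sx, double sy, double sz) {
  NumericVector cur = clone(vol);
  double sig[3] = {sx, sy, sz};
  int dims[3] = {nx, ny, nz};
  for (int axis = 0; axis < 3; ++axis) {
    double s = sig[axis];
    if (s <= 0) continue;
    int r = (int)std::ceil(3.5 * s);
    std::vector<double> w(2 * r + 1);
    double tot = 0;
    for (int i = -r; i <= r; ++i) {
      w[i + r] = std::exp(-0.5 * i * i / (s * s));
      tot += w[i + r];
    }
    for (size_t i = 0; i < w.size(); ++i) w[i] /= tot;
    NumericVector nxt(cur.size());
    int n = dims[axis];
    int stride = (axis == 0) ? 1 : (axis == 1 ? nx : nx * ny);
    // iterate over all lines along `axis`
    for (int z = 0; z < (axis == 2 ? 1 : nz); ++z)
      for (int y = 0; y < (axis == 1 ? 1 : ny); ++y)
        for (int x = 0; x < (axis == 0 ? 1 : nx); ++x) {
          int base = idx3(x, y, z, nx, ny);
          for (int p = 0; p < n; ++p) {
            double acc = 0;
            for (int i = -r; i <= r; ++i) {
              int q = p + i;
              if (q < 0) q = -q - 1;          // reflect
              if (q >= n) q = 2 * n - q - 1;
              if (q < 0) q = 0;                // tiny-axis guard
              if (q >= n) q = n - 1;
              acc += w[i + r] * cur[base + q * stride];
            }
            nxt[base + p * stride] = acc;
          }
        }
    cur = nxt;
  }
  return cur;
}
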