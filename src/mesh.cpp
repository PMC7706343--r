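// Iso-surface triangulation by marching tetrahedra and a 3D convex hull.
//
// Marching tetrahedra splits every grid cell into six tetrahedra sharing the
// cell's main diagonal; each tetrahedron contributes 0, 1 or 2 triangles
// with vertices linearly interpolated on its edges at the iso-level. Shared
// faces between tetrahedra cancel, so the union over a padded field is a
// watertight surface. Chosen over tabulated marching cubes because the case
// analysis is small enough to verify by inspection; the measured quantity
// (triangle area sum) is the same primitive.
#include <Rcpp.h>
#include <vector>
#include <map>
#include <array>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static inline double interp_t(double va, double vb, double level) {
  double d = vb - va;
  if (d == 0.0) return 0.5;
  double t = (level - va) / d;
  if (t < 0.0) t = 0.0;
  if (t > 1.0) t = 1.0;
  return t;
}

struct Vec3 {
  double x, y, z;
};

static inline double tri_area(const Vec3 &a, const Vec3 &b, const Vec3 &c) {
  double ux = b.x - a.x, uy = b.y - a.y, uz = b.z - a.z;
  double vx = c.x - a.x, vy = c.y - a.y, vz = c.z - a.z;
  double cx = uy * vz - uz * vy;
  double cy = uz * vx - ux * vz;
  double cz = ux * vy - uy * vx;
  return 0.5 * std::sqrt(cx * cx + cy * cy + cz * cz);
}

// Sum of triangle areas of the level-set surface, physical units via
// spacing. Also reports triangle count and the number of unmatched triangle
// edges (0 for a closed surface).
// [[Rcpp::export]]
List cpp_isosurface_area(NumericVector field, int nx, int ny, int nz,
                         double level, double dx, double dy, double dz) {
  // cube corner offsets, main diagonal c0 -> c6
  static const int CO[8][3] = {{0,0,0},{1,0,0},{1,1,0},{0,1,0},
                               {0,0,1},{1,0,1},{1,1,1},{0,1,1}};
  static const int TETS[6][4] = {{0,5,1,6},{0,1,2,6},{0,2,3,6},
                                 {0,3,7,6},{0,7,4,6},{0,4,5,6}};
  double area = 0.0;
  int64_t ntri = 0;
  // edge-match accounting on quantized vertex keys
  typedef std::array<int64_t, 3> VK;
  std::map<std::pair<VK, VK>, int> edges;
  double vals[8];
  Vec3 pos[8];
  for (int z = 0; z + 1 < nz; ++z)
    for (int y = 0; y + 1 < ny; ++y)
      for (int x = 0; x + 1 < nx; ++x) {
        bool any_above = false, any_below = false;
        for (int c = 0; c < 8; ++c) {
          int xx = x + CO[c][0], yy = y + CO[c][1], zz = z + CO[c][2];
          vals[c] = field[xx + nx * (yy + (R_xlen_t)ny * zz)];
          pos[c].x = xx * dx; pos[c].y = yy * dy; pos[c].z = zz * dz;
          if (vals[c] > level) any_above = true; else any_below = true;
        }
        if (!any_above || !any_below) continue;
        for (int t = 0; t < 6; ++t) {
          const int *T = TETS[t];
          int above[4], na = 0, nb = 0, below[4];
          for (int c = 0; c < 4; ++c) {
            if (vals[T[c]] > level) above[na++] = T[c];
            else below[nb++] = T[c];
          }
          if (na == 0 || na == 4) continue;
          Vec3 tv[4];
          int nv = 0;
          if (na == 1 || na == 3) {
            int apex = (na == 1) ? above[0] : below[0];
            const int *others = (na == 1) ? below : above;
            for (int c = 0; c < 3; ++c) {
              double tt = interp_t(vals[apex], vals[others[c]], level);
              tv[nv].x = pos[apex].x + tt * (pos[others[c]].x - pos[apex].x);
              tv[nv].y = pos[apex].y + tt * (pos[others[c]].y - pos[apex].y);
              tv[nv].z = pos[apex].z + tt * (pos[others[c]].z - pos[apex].z);
              ++nv;
            }
          } else { // 2-2 split: quad over the four crossing edges
            int a0 = above[0], a1 = above[1], b0 = below[0], b1 = below[1];
            int pairs[4][2] = {{a0, b0}, {a0, b1}, {a1, b1}, {a1, b0}};
            for (int c = 0; c < 4; ++c) {
              int p = pairs[c][0], q = pairs[c][1];
              double tt = interp_t(vals[p], vals[q], level);
              tv[nv].x = pos[p].x + tt * (pos[q].x - pos[p].x);
              tv[nv].y = pos[p].y + tt * (pos[q].y - pos[p].y);
              tv[nv].z = pos[p].z + tt * (pos[q].z - pos[p].z);
              ++nv;
            }
          }
          int tris[2][3] = {{0, 1, 2}, {0, 2, 3}};
          int nt = (nv == 4) ? 2 : 1;
          for (int k = 0; k < nt; ++k) {
            Vec3 &A = tv[tris[k][0]], &B = tv[tris[k][1]], &C = tv[tris[k][2]];
            double ar = tri_area(A, B, C);
            if (ar <= 0.0) continue;
            area += ar;
            ++ntri;
            VK ka = {{(int64_t)llround(A.x * 1e7), (int64_t)llround(A.y * 1e7),
                      (int64_t)llround(A.z * 1e7)}};
            VK kb = {{(int64_t)llround(B.x * 1e7), (int64_t)llround(B.y * 1e7),
                      (int64_t)llround(B.z * 1e7)}};
            VK kc = {{(int64_t)llround(C.x * 1e7), (int64_t)llround(C.y * 1e7),
                      (int64_t)llround(C.z * 1e7)}};
            VK *ks[3] = {&ka, &kb, &kc};
            for (int e = 0; e < 3; ++e) {
              VK u = *ks[e], v = *ks[(e + 1) % 3];
              if (u == v) continue; // degenerate edge from duplicate verts
              std::pair<VK, VK> key = (u < v) ? std::make_pair(u, v)
                                              : std::make_pair(v, u);
              edges[key] += 1;
            }
          }
        }
      }
  int64_t open_edges = 0;
  for (std::map<std::pair<VK, VK>, int>::const_iterator it = edges.begin();
       it != edges.end(); ++it)
    if (it->second % 2 != 0) ++open_edges;
  return List::create(_["area"] = area, _["n_triangles"] = (double)ntri,
                      _["open_edges"] = (double)open_edges);
}

// ---------------------------------------------------------------------------
// Incremental 3D convex hull (beneath-beyond). Points in physical units.
// Returns hull volume; stops with an error for degenerate (coplanar) input.

struct Face {
  int a, b, c;
  double nxv, nyv, nzv, off; // outward normal, plane offset
  bool alive;
};

static void face_plane(Face &f, const std::vector<double> &px,
                       const std::vector<double> &py,
                       const std::vector<double> &pz, double ix, double iy,
                       double iz) {
  double ux = px[f.b] - px[f.a], uy = py[f.b] - py[f.a], uz = pz[f.b] - pz[f.a];
  double vx = px[f.c] - px[f.a], vy = py[f.c] - py[f.a], vz = pz[f.c] - pz[f.a];
  f.nxv = uy * vz - uz * vy;
  f.nyv = uz * vx - ux * vz;
  f.nzv = ux * vy - uy * vx;
  f.off = f.nxv * px[f.a] + f.nyv * py[f.a] + f.nzv * pz[f.a];
  // orient away from the interior reference point
  if (f.nxv * ix + f.nyv * iy + f.nzv * iz > f.off) {
    std::swap(f.b, f.c);
    f.nxv = -f.nxv; f.nyv = -f.nyv; f.nzv = -f.nzv; f.off = -f.off;
  }
}

static void build_hull(NumericMatrix pts, std::vector<Face> &faces,
                       std::vector<double> &px, std::vector<double> &py,
                       std::vector<double> &pz, double &ix, double &iy,
                       double &iz);

// Convex-hull volume of a 3D point cloud.
// [[Rcpp::export]]
double cpp_hull_volume(NumericMatrix pts) {
  std::vector<Face> faces;
  std::vector<double> px, py, pz;
  double ix, iy, iz;
  build_hull(pts, faces, px, py, pz, ix, iy, iz);
  double vol = 0.0;
  for (size_t f = 0; f < faces.size(); ++f) {
    if (!faces[f].alive) continue;
    const Face &fc = faces[f];
    double ax = px[fc.a] - ix, ay = py[fc.a] - iy, az = pz[fc.a] - iz;
    double bx = px[fc.b] - ix, by = py[fc.b] - iy, bz = pz[fc.b] - iz;
    double cx = px[fc.c] - ix, cy = py[fc.c] - iy, cz = pz[fc.c] - iz;
    vol += (ax * (by * cz - bz * cy) - ay * (bx * cz - bz * cx) +
            az * (bx * cy - by * cx)) / 6.0;
  }
  return std::fabs(vol);
}

// 1-based indices of the points that are hull vertices.
// [[Rcpp::export]]
IntegerVector cpp_hull_vertices(NumericMatrix pts) {
  std::vector<Face> faces;
  std::vector<double> px, py, pz;
  double ix, iy, iz;
  build_hull(pts, faces, px, py, pz, ix, iy, iz);
  std::vector<bool> used(pts.nrow(), false);
  for (size_t f = 0; f < faces.size(); ++f)
    if (faces[f].alive) {
      used[faces[f].a] = true;
      used[faces[f].b] = true;
      used[faces[f].c] = true;
    }
  std::vector<int> out;
  for (int i = 0; i < pts.nrow(); ++i)
    if (used[i]) out.push_back(i + 1);
  return wrap(out);
}

// Which query points lie inside (or on, within tolerance) the convex hull
// of `pts`.
// [[Rcpp::export]]
LogicalVector cpp_points_in_hull(NumericMatrix pts, NumericMatrix queries) {
  std::vector<Face> faces;
  std::vector<double> px, py, pz;
  double ix, iy, iz;
  build_hull(pts, faces, px, py, pz, ix, iy, iz);
  double scale = 1.0;
  for (size_t i = 0; i < px.size(); ++i) {
    scale = std::max(scale, std::fabs(px[i]));
    scale = std::max(scale, std::fabs(py[i]));
    scale = std::max(scale, std::fabs(pz[i]));
  }
  int nq = queries.nrow();
  std::vector<double> nn(faces.size(), 0.0);
  for (size_t f = 0; f < faces.size(); ++f)
    nn[f] = std::sqrt(faces[f].nxv * faces[f].nxv +
                      faces[f].nyv * faces[f].nyv +
                      faces[f].nzv * faces[f].nzv);
  LogicalVector out(nq);
  for (int q = 0; q < nq; ++q) {
    bool inside = true;
    for (size_t f = 0; f < faces.size() && inside; ++f) {
      if (!faces[f].alive || nn[f] == 0.0) continue;
      double d = faces[f].nxv * queries(q, 0) + faces[f].nyv * queries(q, 1) +
                 faces[f].nzv * queries(q, 2) - faces[f].off;
      if (d > 1e-8 * scale * nn[f]) inside = false;
    }
    out[q] = inside;
  }
  return out;
}

static void build_hull(NumericMatrix pts, std::vector<Face> &faces,
                       std::vector<double> &pxr, std::vector<double> &pyr,
                       std::vector<double> &pzr, double &ixr, double &iyr,
                       double &izr) {
  int n = pts.nrow();
  if (n < 4) stop("need at least 4 points for a 3D hull");
  pxr.assign(n, 0.0); pyr.assign(n, 0.0); pzr.assign(n, 0.0);
  std::vector<double> &px = pxr, &py = pyr, &pz = pzr;
  double scale = 0.0;
  for (int i = 0; i < n; ++i) {
    px[i] = pts(i, 0); py[i] = pts(i, 1); pz[i] = pts(i, 2);
    scale = std::max(scale, std::fabs(px[i]));
    scale = std::max(scale, std::fabs(py[i]));
    scale = std::max(scale, std::fabs(pz[i]));
  }
  if (scale == 0.0) scale = 1.0;
  double eps = 1e-10 * scale * scale; // area-scale tolerance for visibility
  // initial simplex: extremes along x, then farthest point pairs
  int i0 = 0, i1 = 0;
  for (int i = 0; i < n; ++i) {
    if (px[i] < px[i0]) i0 = i;
    if (px[i] > px[i1]) i1 = i;
  }
  if (i0 == i1) i1 = (i0 + 1) % n;
  int i2 = -1;
  double best = -1;
  for (int i = 0; i < n; ++i) {
    double ux = px[i1] - px[i0], uy = py[i1] - py[i0], uz = pz[i1] - pz[i0];
    double vx = px[i] - px[i0], vy = py[i] - py[i0], vz = pz[i] - pz[i0];
    double cx = uy * vz - uz * vy, cy = uz * vx - ux * vz, cz = ux * vy - uy * vx;
    double a2 = cx * cx + cy * cy + cz * cz;
    if (a2 > best) { best = a2; i2 = i; }
  }
  if (best <= eps * eps) stop("degenerate hull: points are collinear");
  Face f0; f0.a = i0; f0.b = i1; f0.c = i2;
  double n0x, n0y, n0z, off0;
  {
    double ux = px[i1] - px[i0], uy = py[i1] - py[i0], uz = pz[i1] - pz[i0];
    double vx = px[i2] - px[i0], vy = py[i2] - py[i0], vz = pz[i2] - pz[i0];
    n0x = uy * vz - uz * vy; n0y = uz * vx - ux * vz; n0z = ux * vy - uy * vx;
    off0 = n0x * px[i0] + n0y * py[i0] + n0z * pz[i0];
  }
  int i3 = -1;
  best = -1;
  for (int i = 0; i < n; ++i) {
    double d = std::fabs(n0x * px[i] + n0y * py[i] + n0z * pz[i] - off0);
    if (d > best) { best = d; i3 = i; }
  }
  if (best <= eps) stop("degenerate hull: points are coplanar");
  double &ix = ixr, &iy = iyr, &iz = izr;
  ix = (px[i0] + px[i1] + px[i2] + px[i3]) / 4.0;
  iy = (py[i0] + py[i1] + py[i2] + py[i3]) / 4.0;
  iz = (pz[i0] + pz[i1] + pz[i2] + pz[i3]) / 4.0;
  faces.clear();
  int quad[4][3] = {{i0, i1, i2}, {i0, i1, i3}, {i0, i2, i3}, {i1, i2, i3}};
  for (int k = 0; k < 4; ++k) {
    Face f; f.a = quad[k][0]; f.b = quad[k][1]; f.c = quad[k][2]; f.alive = true;
    face_plane(f, px, py, pz, ix, iy, iz);
    faces.push_back(f);
  }
  std::vector<int> visible;
  for (int p = 0; p < n; ++p) {
    if (p == i0 || p == i1 || p == i2 || p == i3) continue;
    visible.clear();
    for (size_t f = 0; f < faces.size(); ++f) {
      if (!faces[f].alive) continue;
      double d = faces[f].nxv * px[p] + faces[f].nyv * py[p] +
                 faces[f].nzv * pz[p] - faces[f].off;
      if (d > eps) visible.push_back((int)f);
    }
    if (visible.empty()) continue;
    // horizon = edges of visible faces adjacent to exactly one visible face
    std::map<std::pair<int, int>, int> ecount;
    for (size_t t = 0; t < visible.size(); ++t) {
      Face &f = faces[visible[t]];
      int vs[3][2] = {{f.a, f.b}, {f.b, f.c}, {f.c, f.a}};
      for (int e = 0; e < 3; ++e) {
        std::pair<int, int> key(std::min(vs[e][0], vs[e][1]),
                                std::max(vs[e][0], vs[e][1]));
        ecount[key] += 1;
      }
      f.alive = false;
    }
    for (std::map<std::pair<int, int>, int>::iterator it = ecount.begin();
         it != ecount.end(); ++it) {
      if (it->second != 1) continue;
      Face f;
      f.a = it->first.first; f.b = it->first.second; f.c = p; f.alive = true;
      face_plane(f, px, py, pz, ix, iy, iz);
      faces.push_back(f);
    }
  }
}
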