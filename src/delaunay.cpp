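// 3D Delaunay triangulation (Bowyer-Watson, incremental with walk-based point
// location) used for convex-hull and alpha-shape volumes of crown point clouds.
//
// Predicates are evaluated on coordinates normalised to the unit box and
// symbolically perturbed by a tiny deterministic per-index jitter so that
// degenerate inputs (grids, cospherical corners) triangulate consistently.
// Volumes and circumradii are measured on the ORIGINAL coordinates, so the
// reported geometry is unaffected by the jitter beyond O(1e-9) of the scale.
//
// Alpha-shape convention: a tetrahedron belongs to the alpha complex iff its
// circumsphere radius is strictly smaller than alpha (alpha = radius bound,
// the convention of the CGAL/alphashape3d family). The union of retained
// tetrahedra over all of Delaunay is the convex hull, so
// alpha_volume(alpha) -> hull_volume as alpha -> Inf and is monotone in alpha.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <map>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Tet {
  int v[4];   // vertex indices
  int nb[4];  // neighbour opposite v[i]; -1 = none
  bool alive;
};

typedef std::array<double, 3> P3;

inline double orient3d(const P3 &a, const P3 &b, const P3 &c, const P3 &d) {
  double b0 = b[0] - a[0], b1 = b[1] - a[1], b2 = b[2] - a[2];
  double c0 = c[0] - a[0], c1 = c[1] - a[1], c2 = c[2] - a[2];
  double d0 = d[0] - a[0], d1 = d[1] - a[1], d2 = d[2] - a[2];
  return b0 * (c1 * d2 - c2 * d1) - b1 * (c0 * d2 - c2 * d0) +
         b2 * (c0 * d1 - c1 * d0);
}

// 4x4 determinant with rows (a-e, |a-e|^2) ... (d-e, |d-e|^2)
inline double insphere_det(const P3 &a, const P3 &b, const P3 &c, const P3 &d,
                           const P3 &e) {
  double ax = a[0] - e[0], ay = a[1] - e[1], az = a[2] - e[2];
  double bx = b[0] - e[0], by = b[1] - e[1], bz = b[2] - e[2];
  double cx = c[0] - e[0], cy = c[1] - e[1], cz = c[2] - e[2];
  double dx = d[0] - e[0], dy = d[1] - e[1], dz = d[2] - e[2];
  double an = ax * ax + ay * ay + az * az;
  double bn = bx * bx + by * by + bz * bz;
  double cn = cx * cx + cy * cy + cz * cz;
  double dn = dx * dx + dy * dy + dz * dz;
  double ab = ax * by - bx * ay, bc = bx * cy - cx * by;
  double cd = cx * dy - dx * cy, da = dx * ay - ax * dy;
  double ac = ax * cy - cx * ay, bd = bx * dy - dx * by;
  double abc = az * bc - bz * ac + cz * ab;
  double bcd = bz * cd - cz * bd + dz * bc;
  double cda = cz * da + dz * ac + az * cd;
  double dab = dz * ab + az * bd + bz * da;
  return dn * abc - cn * dab + bn * cda - an * bcd;
}

// parity so that (orient > 0, point inside circumsphere) => sign * det > 0,
// fixed once from a known configuration (regular tetrahedron + its centroid).
double insphere_parity() {
  P3 a = {0.0, 0.0, 0.0}, b = {1.0, 0.0, 0.0}, c = {0.0, 1.0, 0.0},
     d = {0.0, 0.0, 1.0};
  P3 e = {0.25, 0.25, 0.25};  // centroid, inside
  double o = orient3d(a, b, c, d);
  double s = insphere_det(a, b, c, d, e);
  return (o > 0 ? 1.0 : -1.0) * (s > 0 ? 1.0 : -1.0);
}

// deterministic jitter in [-1, 1] from point index and axis (splitmix64)
inline double jitter_unit(uint64_t i, uint64_t axis) {
  uint64_t z = i * 0x9E3779B97F4A7C15ULL + axis * 0xBF58476D1CE4E5B9ULL + 1ULL;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  z = z ^ (z >> 31);
  return (double)(z >> 11) / (double)(1ULL << 53) * 2.0 - 1.0;
}

struct Triangulator {
  std::vector<P3> q;  // normalised + jittered coords (incl. 4 super vertices)
  std::vector<Tet> tets;
  int n;  // number of real points
  double parity;
  int last_alive;

  bool inside_sphere(const Tet &t, int pi) const {
    const P3 &a = q[t.v[0]], &b = q[t.v[1]], &c = q[t.v[2]], &d = q[t.v[3]];
    double o = orient3d(a, b, c, d);
    double s = insphere_det(a, b, c, d, q[pi]);
    double val = (o >= 0 ? 1.0 : -1.0) * parity * s;
    return val > 0;
  }

  // is p on the opposite side of face i (vs the face's opposite vertex)?
  int walk_next(int ti, int pi) const {
    const Tet &t = tets[ti];
    static const int F[4][3] = {{1, 2, 3}, {0, 2, 3}, {0, 1, 3}, {0, 1, 2}};
    for (int i = 0; i < 4; ++i) {
      const P3 &fa = q[t.v[F[i][0]]], &fb = q[t.v[F[i][1]]],
               &fc = q[t.v[F[i][2]]];
      double oref = orient3d(fa, fb, fc, q[t.v[i]]);
      double op = orient3d(fa, fb, fc, q[pi]);
      if (oref * op < 0) return t.nb[i];
    }
    return -1;  // inside
  }

  int locate(int pi) {
    int ti = last_alive;
    if (ti < 0 || !tets[ti].alive) {
      for (int k = (int)tets.size() - 1; k >= 0; --k)
        if (tets[k].alive) { ti = k; break; }
    }
    size_t steps = 0, maxsteps = tets.size() * 4 + 64;
    while (true) {
      int nx = walk_next(ti, pi);
      if (nx < 0) return ti;
      ti = nx;
      if (++steps > maxsteps) break;
    }
    // fallback: exhaustive scan (degenerate walk cycles)
    for (int k = 0; k < (int)tets.size(); ++k)
      if (tets[k].alive && walk_next(k, pi) < 0) return k;
    stop("point location failed (degenerate input?)");
    return -1;
  }

  void insert(int pi) {
    int seed_tet = locate(pi);
    // BFS the cavity of tets whose circumsphere contains pi
    std::vector<int> cavity;
    std::vector<int> stack;
    std::vector<char> in_cav(tets.size(), 0);
    stack.push_back(seed_tet);
    in_cav[seed_tet] = 1;
    while (!stack.empty()) {
      int ti = stack.back();
      stack.pop_back();
      cavity.push_back(ti);
      for (int i = 0; i < 4; ++i) {
        int nb = tets[ti].nb[i];
        if (nb >= 0 && !in_cav[nb] && tets[nb].alive &&
            inside_sphere(tets[nb], pi)) {
          in_cav[nb] = 1;
          stack.push_back(nb);
        }
      }
    }
    // boundary faces of the cavity
    static const int F[4][3] = {{1, 2, 3}, {0, 2, 3}, {0, 1, 3}, {0, 1, 2}};
    struct BFace { int a, b, c, outside, out_slot; };
    std::vector<BFace> faces;
    for (int ti : cavity) {
      for (int i = 0; i < 4; ++i) {
        int nb = tets[ti].nb[i];
        if (nb < 0 || !in_cav[nb]) {
          BFace f;
          f.a = tets[ti].v[F[i][0]];
          f.b = tets[ti].v[F[i][1]];
          f.c = tets[ti].v[F[i][2]];
          f.outside = nb;
          f.out_slot = -1;
          if (nb >= 0) {
            for (int j = 0; j < 4; ++j)
              if (tets[nb].nb[j] == ti) f.out_slot = j;
          }
          faces.push_back(f);
        }
      }
    }
    for (int ti : cavity) tets[ti].alive = false;
    // new tets: pi + each boundary face, linked through a map on edges of the
    // boundary polyhedron (each new internal face contains pi and one edge)
    std::map<std::pair<int, int>, std::pair<int, int> > edge_map;
    for (const BFace &f : faces) {
      Tet t;
      t.v[0] = pi;
      t.v[1] = f.a; t.v[2] = f.b; t.v[3] = f.c;
      if (orient3d(q[t.v[0]], q[t.v[1]], q[t.v[2]], q[t.v[3]]) < 0)
        std::swap(t.v[2], t.v[3]);
      t.nb[0] = f.outside;
      t.nb[1] = t.nb[2] = t.nb[3] = -1;
      t.alive = true;
      int ni = (int)tets.size();
      tets.push_back(t);
      in_cav.push_back(0);
      if (f.outside >= 0 && f.out_slot >= 0) tets[f.outside].nb[f.out_slot] = ni;
      // register the three internal faces via their boundary edge
      for (int slot = 1; slot <= 3; ++slot) {
        int e1 = tets[ni].v[slot == 1 ? 2 : 1];
        int e2 = tets[ni].v[slot == 3 ? 2 : 3];
        std::pair<int, int> key(std::min(e1, e2), std::max(e1, e2));
        std::map<std::pair<int, int>, std::pair<int, int> >::iterator it =
            edge_map.find(key);
        if (it == edge_map.end()) {
          edge_map[key] = std::make_pair(ni, slot);
        } else {
          int oi = it->second.first, oslot = it->second.second;
          tets[ni].nb[slot] = oi;
          tets[oi].nb[oslot] = ni;
          edge_map.erase(it);
        }
      }
      last_alive = ni;
    }
    if (!edge_map.empty())
      stop("cavity retriangulation failed (unmatched faces)");
  }
};

inline double tet_volume(const double *a, const double *b, const double *c,
                         const double *d) {
  double b0 = b[0] - a[0], b1 = b[1] - a[1], b2 = b[2] - a[2];
  double c0 = c[0] - a[0], c1 = c[1] - a[1], c2 = c[2] - a[2];
  double d0 = d[0] - a[0], d1 = d[1] - a[1], d2 = d[2] - a[2];
  double det = b0 * (c1 * d2 - c2 * d1) - b1 * (c0 * d2 - c2 * d0) +
               b2 * (c0 * d1 - c1 * d0);
  return std::fabs(det) / 6.0;
}

// circumradius from the linear system 2(b-a).x = |b|^2-|a|^2 etc.
inline double circumradius(const double *a, const double *b, const double *c,
                           const double *d) {
  double M[3][3], r[3];
  const double *pts[3] = {b, c, d};
  for (int i = 0; i < 3; ++i) {
    double s = 0;
    for (int j = 0; j < 3; ++j) {
      M[i][j] = 2.0 * (pts[i][j] - a[j]);
      s += pts[i][j] * pts[i][j] - a[j] * a[j];
    }
    r[i] = s;
  }
  double det = M[0][0] * (M[1][1] * M[2][2] - M[1][2] * M[2][1]) -
               M[0][1] * (M[1][0] * M[2][2] - M[1][2] * M[2][0]) +
               M[0][2] * (M[1][0] * M[2][1] - M[1][1] * M[2][0]);
  if (std::fabs(det) < 1e-300) return R_PosInf;  // flat tet
  double x[3];
  x[0] = (r[0] * (M[1][1] * M[2][2] - M[1][2] * M[2][1]) -
          M[0][1] * (r[1] * M[2][2] - M[1][2] * r[2]) +
          M[0][2] * (r[1] * M[2][1] - M[1][1] * r[2])) / det;
  x[1] = (M[0][0] * (r[1] * M[2][2] - M[1][2] * r[2]) -
          r[0] * (M[1][0] * M[2][2] - M[1][2] * M[2][0]) +
          M[0][2] * (M[1][0] * r[2] - r[1] * M[2][0])) / det;
  x[2] = (M[0][0] * (M[1][1] * r[2] - r[1] * M[2][1]) -
          M[0][1] * (M[1][0] * r[2] - r[1] * M[2][0]) +
          r[0] * (M[1][0] * M[2][1] - M[1][1] * M[2][0])) / det;
  double dx = a[0] - x[0], dy = a[1] - x[1], dz = a[2] - x[2];
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

}  // namespace

//' @title 3D Delaunay tetrahedra of a point set (internal)
//' @description Returns one row per Delaunay tetrahedron: the four 1-based
//'   vertex indices, the tetrahedron volume and its circumsphere radius, both
//'   measured in the units of the input coordinates.
//' @param pts numeric matrix (n x 3)
//' @return numeric matrix (m x 6): i1, i2, i3, i4, volume, circumradius
//' @keywords internal
// [[Rcpp::export(name = ".delaunay_tets")]]
NumericMatrix delaunay_tets(NumericMatrix pts) {
  int n = pts.nrow();
  if (pts.ncol() != 3) stop("points must be an n x 3 matrix");
  if (n < 4) stop("need at least 4 points for a 3D triangulation");

  // normalise to unit box
  double lo[3], hi[3];
  for (int j = 0; j < 3; ++j) { lo[j] = R_PosInf; hi[j] = R_NegInf; }
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 3; ++j) {
      double v = pts(i, j);
      if (!R_finite(v)) stop("non-finite coordinate");
      if (v < lo[j]) lo[j] = v;
      if (v > hi[j]) hi[j] = v;
    }
  double scale = 0.0;
  for (int j = 0; j < 3; ++j) scale = std::max(scale, hi[j] - lo[j]);
  if (scale <= 0) stop("degenerate point cloud (all points coincide)");

  Triangulator T;
  T.n = n;
  T.parity = insphere_parity();
  T.last_alive = -1;
  T.q.resize(n + 4);
  const double JIT = 1e-9;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 3; ++j)
      T.q[i][j] = (pts(i, j) - lo[j]) / scale +
                  JIT * jitter_unit((uint64_t)i + 1, (uint64_t)j + 1);
  // super-tetrahedron: alternate corners of a large cube around the unit box
  double R = 1e4;
  double ctr = 0.5;
  double sv[4][3] = {{ctr + R, ctr + R, ctr + R},
                     {ctr + R, ctr - R, ctr - R},
                     {ctr - R, ctr + R, ctr - R},
                     {ctr - R, ctr - R, ctr + R}};
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 3; ++j) T.q[n + i][j] = sv[i][j];
  Tet super;
  super.v[0] = n; super.v[1] = n + 1; super.v[2] = n + 2; super.v[3] = n + 3;
  if (orient3d(T.q[super.v[0]], T.q[super.v[1]], T.q[super.v[2]],
               T.q[super.v[3]]) < 0)
    std::swap(super.v[2], super.v[3]);
  super.nb[0] = super.nb[1] = super.nb[2] = super.nb[3] = -1;
  super.alive = true;
  T.tets.push_back(super);
  T.last_alive = 0;

  // deterministic shuffled insertion order (independent of R's RNG)
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  uint64_t st = 0x853C49E6748FEA9BULL;
  for (int i = n - 1; i > 0; --i) {
    st = st * 6364136223846793005ULL + 1442695040888963407ULL;
    int k = (int)(st % (uint64_t)(i + 1));
    std::swap(order[i], order[k]);
  }
  for (int i = 0; i < n; ++i) {
    T.insert(order[i]);
    if ((i & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  // collect real tets, measure on original coordinates
  std::vector<std::array<double, 6> > out;
  std::vector<double> orig(3 * n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 3; ++j) orig[3 * i + j] = pts(i, j);
  for (size_t k = 0; k < T.tets.size(); ++k) {
    const Tet &t = T.tets[k];
    if (!t.alive) continue;
    if (t.v[0] >= n || t.v[1] >= n || t.v[2] >= n || t.v[3] >= n) continue;
    const double *a = &orig[3 * t.v[0]], *b = &orig[3 * t.v[1]],
                 *c = &orig[3 * t.v[2]], *d = &orig[3 * t.v[3]];
    std::array<double, 6> row;
    row[0] = t.v[0] + 1; row[1] = t.v[1] + 1;
    row[2] = t.v[2] + 1; row[3] = t.v[3] + 1;
    row[4] = tet_volume(a, b, c, d);
    row[5] = circumradius(a, b, c, d);
    out.push_back(row);
  }
  NumericMatrix res((int)out.size(), 6);
  for (int i = 0; i < (int)out.size(); ++i)
    for (int j = 0; j < 6; ++j) res(i, j) = out[i][j];
  colnames(res) = CharacterVector::create("i1", "i2", "i3", "i4", "volume",
                                          "circumradius");
  return res;
}
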