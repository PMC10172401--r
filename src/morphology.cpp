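#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// ---- 3-D curve thinning --------------------------------------------------
// Sequential simple-point removal with endpoint preservation. A border
// voxel is deletable when removing it preserves local topology:
//   (a) the object voxels of N26 \ {p} form exactly one 26-connected
//       component, and
//   (b) the background voxels of N18 that are 6-adjacent to p form exactly
//       one 6-connected component within N18.
// Voxels with at most one object neighbor (curve endpoints) are kept.
// Deletion proceeds in 6 directional sub-iterations (U/D/N/S/E/W border
// passes) with the simple-point test re-evaluated at deletion time, which
// keeps the peeling order-safe; iteration stops at a fixed point.

static const int d6[6][3] = {
  {1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}
};

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

static int neighbor_count26(const std::vector<char> &v, int x, int y, int z,
                            int nx, int ny, int nz) {
  int cnt = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (!dx && !dy && !dz) continue;
        int X = x + dx, Y = y + dy, Z = z + dz;
        if (X < 0 || Y < 0 || Z < 0 || X >= nx || Y >= ny || Z >= nz) continue;
        if (v[idx3(X, Y, Z, nx, ny)]) ++cnt;
      }
  return cnt;
}

// local 3x3x3 cube of the neighborhood (center excluded by caller)
static void fill_cube(const std::vector<char> &v, int x, int y, int z,
                      int nx, int ny, int nz, char cube[27]) {
  int k = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx, ++k) {
        int X = x + dx, Y = y + dy, Z = z + dz;
        if (X < 0 || Y < 0 || Z < 0 || X >= nx || Y >= ny || Z >= nz)
          cube[k] = 0;
        else
          cube[k] = v[idx3(X, Y, Z, nx, ny)];
      }
}

static inline int cpos(int dx, int dy, int dz) {
  return (dx + 1) + 3 * ((dy + 1) + 3 * (dz + 1));
}

// count 26-connected components of object voxels in N26 (center removed)
static int cc26_object(const char cube_in[27]) {
  char cube[27];
  for (int i = 0; i < 27; ++i) cube[i] = cube_in[i];
  cube[13] = 0; // remove center
  int ncomp = 0;
  int stack[27];
  for (int s = 0; s < 27; ++s) {
    if (!cube[s]) continue;
    ++ncomp;
    int top = 0; stack[top++] = s; cube[s] = 0;
    while (top) {
      int c = stack[--top];
      int cx = c % 3, cy = (c / 3) % 3, cz = c / 9;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            int X = cx + dx, Y = cy + dy, Z = cz + dz;
            if (X < 0 || Y < 0 || Z < 0 || X > 2 || Y > 2 || Z > 2) continue;
            int q = X + 3 * Y + 9 * Z;
            if (cube[q]) { cube[q] = 0; stack[top++] = q; }
          }
    }
  }
  return ncomp;
}

// count 6-connected components of background voxels of N18 that touch a
// 6-neighbor of the center; connectivity restricted to N18
static int cc6_background(const char cube_in[27]) {
  // N18: offsets with |dx|+|dy|+|dz| <= 2 and not all zero, excluding corners
  bool in18[27];
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int k = cpos(dx, dy, dz);
        int man = std::abs(dx) + std::abs(dy) + std::abs(dz);
        in18[k] = (man >= 1 && man <= 2);
      }
  char bg[27];
  for (int i = 0; i < 27; ++i) bg[i] = (in18[i] && !cube_in[i]) ? 1 : 0;
  // seeds: 6-neighbors of center that are background
  int ncomp = 0;
  int stack[27];
  bool seen[27] = {false};
  for (int s6 = 0; s6 < 6; ++s6) {
    int seed = cpos(d6[s6][0], d6[s6][1], d6[s6][2]);
    if (!bg[seed] || seen[seed]) continue;
    ++ncomp;
    int top = 0; stack[top++] = seed; seen[seed] = true;
    while (top) {
      int c = stack[--top];
      int cx = c % 3 - 1, cy = (c / 3) % 3 - 1, cz = c / 9 - 1;
      for (int m = 0; m < 6; ++m) {
        int X = cx + d6[m][0], Y = cy + d6[m][1], Z = cz + d6[m][2];
        if (X < -1 || Y < -1 || Z < -1 || X > 1 || Y > 1 || Z > 1) continue;
        int q = cpos(X, Y, Z);
        if (bg[q] && !seen[q]) { seen[q] = true; stack[top++] = q; }
      }
    }
  }
  return ncomp;
}

static bool is_simple(const std::vector<char> &v, int x, int y, int z,
                      int nx, int ny, int nz) {
  char cube[27];
  fill_cube(v, x, y, z, nx, ny, nz, cube);
  return cc26_object(cube) == 1 && cc6_background(cube) == 1;
}

// [[Rcpp::export(name = ".cpp_thin_skeleton")]]
LogicalVector cpp_thin_skeleton(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  std::vector<char> v(n);
  for (int i = 0; i < n; ++i) v[i] = mask[i] ? 1 : 0;

  bool changed = true;
  std::vector<int> cand;
  while (changed) {
    changed = false;
    for (int dir = 0; dir < 6; ++dir) {
      cand.clear();
      for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
          for (int x = 0; x < nx; ++x) {
            int id = idx3(x, y, z, nx, ny);
            if (!v[id]) continue;
            int X = x + d6[dir][0], Y = y + d6[dir][1], Z = z + d6[dir][2];
            bool border = (X < 0 || Y < 0 || Z < 0 ||
                           X >= nx || Y >= ny || Z >= nz) ||
                          !v[idx3(X, Y, Z, nx, ny)];
            // endpoint status is frozen at pass start: existing curve tips
            // survive, while voxels exposed during the pass stay erodable
            if (border && neighbor_count26(v, x, y, z, nx, ny, nz) > 1)
              cand.push_back(id);
          }
      for (size_t k = 0; k < cand.size(); ++k) {
        int id = cand[k];
        if (!v[id]) continue;
        int x = id % nx, y = (id / nx) % ny, z = id / (nx * ny);
        if (is_simple(v, x, y, z, nx, ny, nz)) {
          v[id] = 0;
          changed = true;
        }
      }
    }
  }
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) out[i] = v[i] != 0;
  out.attr("dim") = dims;
  return out;
}

// ---- point-to-triangle distances ----------------------------------------
// Closest-point distance from each query point to a triangle soup
// (Ericson, Real-Time Collision Detection, ch. 5.1.5).

static double pt_tri_dist2(const double p[3], const double a[3],
                           const double b[3], const double c[3]) {
  double ab[3], ac[3], ap[3];
  for (int k = 0; k < 3; ++k) {
    ab[k] = b[k] - a[k]; ac[k] = c[k] - a[k]; ap[k] = p[k] - a[k];
  }
  double d1 = ab[0]*ap[0] + ab[1]*ap[1] + ab[2]*ap[2];
  double d2 = ac[0]*ap[0] + ac[1]*ap[1] + ac[2]*ap[2];
  double q[3];
  if (d1 <= 0.0 && d2 <= 0.0) { for (int k = 0; k < 3; ++k) q[k] = a[k]; goto done; }
  {
    double bp[3];
    for (int k = 0; k < 3; ++k) bp[k] = p[k] - b[k];
    double d3 = ab[0]*bp[0] + ab[1]*bp[1] + ab[2]*bp[2];
    double d4 = ac[0]*bp[0] + ac[1]*bp[1] + ac[2]*bp[2];
    if (d3 >= 0.0 && d4 <= d3) { for (int k = 0; k < 3; ++k) q[k] = b[k]; goto done; }
    double vc = d1 * d4 - d3 * d2;
    if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
      double w = d1 / (d1 - d3);
      for (int k = 0; k < 3; ++k) q[k] = a[k] + w * ab[k];
      goto done;
    }
    double cp[3];
    for (int k = 0; k < 3; ++k) cp[k] = p[k] - c[k];
    double d5 = ab[0]*cp[0] + ab[1]*cp[1] + ab[2]*cp[2];
    double d6_ = ac[0]*cp[0] + ac[1]*cp[1] + ac[2]*cp[2];
    if (d6_ >= 0.0 && d5 <= d6_) { for (int k = 0; k < 3; ++k) q[k] = c[k]; goto done; }
    double vb = d5 * d2 - d1 * d6_;
    if (vb <= 0.0 && d2 >= 0.0 && d6_ <= 0.0) {
      double w = d2 / (d2 - d6_);
      for (int k = 0; k < 3; ++k) q[k] = a[k] + w * ac[k];
      goto done;
    }
    double va = d3 * d6_ - d5 * d4;
    if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6_) >= 0.0) {
      double w = (d4 - d3) / ((d4 - d3) + (d5 - d6_));
      for (int k = 0; k < 3; ++k) q[k] = b[k] + w * (c[k] - b[k]);
      goto done;
    }
    {
      double denom = 1.0 / (va + vb + vc);
      double v_ = vb * denom, w_ = vc * denom;
      for (int k = 0; k < 3; ++k) q[k] = a[k] + ab[k] * v_ + ac[k] * w_;
    }
  }
done:
  double dx = p[0]-q[0], dy = p[1]-q[1], dz = p[2]-q[2];
  return dx*dx + dy*dy + dz*dz;
}

// [[Rcpp::export(name = ".cpp_min_point_tri_dist")]]
NumericVector cpp_min_point_tri_dist(NumericMatrix points,
                                     NumericMatrix v1, NumericMatrix v2,
                                     NumericMatrix v3) {
  int np = points.nrow(), nt = v1.nrow();
  NumericVector out(np);
  for (int i = 0; i < np; ++i) {
    double p[3] = { points(i,0), points(i,1), points(i,2) };
    double best = R_PosInf;
    for (int t = 0; t < nt; ++t) {
      double a[3] = { v1(t,0), v1(t,1), v1(t,2) };
      double b[3] = { v2(t,0), v2(t,1), v2(t,2) };
      double c[3] = { v3(t,0), v3(t,1), v3(t,2) };
      double d2 = pt_tri_dist2(p, a, b, c);
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
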