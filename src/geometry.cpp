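// Low-level geometry kernels: z-column parity voxelization of triangle
// meshes, exact Euclidean distance transforms (Felzenszwalb & Huttenlocher),
// nearest-neighbour point-set distances on a uniform grid, voxel boundary
// surface extraction, and point-to-triangle distances.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cmath>
#include <limits>

using namespace Rcpp;

static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

// ---------------------------------------------------------------------------
// Voxelization: a voxel is inside iff its centre is inside the closed surface
// (parity of ray crossings along +z). Rays are offset by a tiny sub-voxel
// amount so they cannot run through lattice-aligned edges of axis-aligned
// (voxel-boundary) meshes; retries with alternative offsets resolve any
// residual degenerate column.
// ---------------------------------------------------------------------------

// count crossings of the vertical line (rx, ry) with triangle t; append z's
static bool column_crossings(const NumericMatrix& V, const IntegerMatrix& F,
                             const std::vector<int>& tris,
                             double rx, double ry,
                             std::vector<double>& zs) {
  zs.clear();
  for (size_t m = 0; m < tris.size(); ++m) {
    int t = tris[m];
    int i0 = F(t, 0), i1 = F(t, 1), i2 = F(t, 2);
    double ax = V(i0, 0), ay = V(i0, 1), az = V(i0, 2);
    double bx = V(i1, 0), by = V(i1, 1), bz = V(i1, 2);
    double cx = V(i2, 0), cy = V(i2, 1), cz = V(i2, 2);
    double d = (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
    if (d == 0.0) continue;  // face parallel to the ray
    double u = ((rx - ax) * (cy - ay) - (ry - ay) * (cx - ax)) / d;
    double v = ((bx - ax) * (ry - ay) - (by - ay) * (rx - ax)) / d;
    if (u < 0.0 || v < 0.0 || u + v > 1.0) continue;
    if (u == 0.0 || v == 0.0 || u + v == 1.0) return false;  // exact edge hit
    zs.push_back(az + u * (bz - az) + v * (cz - az));
  }
  return true;
}

// [[Rcpp::export]]
LogicalVector cpp_voxelize(NumericMatrix V, IntegerMatrix F,
                           NumericVector origin, NumericVector spacing,
                           IntegerVector shape) {
  const int nx = shape[0], ny = shape[1], nz = shape[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const int nt = F.nrow();

  LogicalVector out((R_xlen_t)nx * ny * nz);
  std::fill(out.begin(), out.end(), FALSE);

  // bin triangles by the grid columns their xy bounding box overlaps
  std::vector<std::vector<int>> cols((size_t)nx * ny);
  for (int t = 0; t < nt; ++t) {
    double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
    for (int k = 0; k < 3; ++k) {
      double x = V(F(t, k), 0), y = V(F(t, k), 1);
      xmin = std::min(xmin, x); xmax = std::max(xmax, x);
      ymin = std::min(ymin, y); ymax = std::max(ymax, y);
    }
    int i0 = std::max(0, (int)std::floor((xmin - ox) / sx - 1.0));
    int i1 = std::min(nx - 1, (int)std::ceil((xmax - ox) / sx));
    int j0 = std::max(0, (int)std::floor((ymin - oy) / sy - 1.0));
    int j1 = std::min(ny - 1, (int)std::ceil((ymax - oy) / sy));
    for (int j = j0; j <= j1; ++j)
      for (int i = i0; i <= i1; ++i)
        cols[(size_t)j * nx + i].push_back(t);
  }

  const double offs[4][2] = {{7.1e-4, 11.3e-4}, {3.7e-4, 5.9e-4},
                             {13.1e-4, 2.3e-4}, {17.3e-4, 19.9e-4}};
  std::vector<double> zs;
  int bad_columns = 0;
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      const std::vector<int>& tris = cols[(size_t)j * nx + i];
      if (tris.empty()) continue;
      bool ok = false;
      for (int a = 0; a < 4 && !ok; ++a) {
        double rx = ox + (i + 0.5 + offs[a][0]) * sx;
        double ry = oy + (j + 0.5 + offs[a][1]) * sy;
        ok = column_crossings(V, F, tris, rx, ry, zs) && zs.size() % 2 == 0;
      }
      if (!ok) { ++bad_columns; continue; }
      std::sort(zs.begin(), zs.end());
      for (size_t m = 0; m + 1 < zs.size(); m += 2) {
        // voxel centres strictly between the entry and exit crossing
        int k0 = (int)std::floor((zs[m] - oz) / sz - 0.5) + 1;
        int k1 = (int)std::ceil((zs[m + 1] - oz) / sz - 0.5) - 1;
        k0 = std::max(k0, 0);
        k1 = std::min(k1, nz - 1);
        for (int k = k0; k <= k1; ++k)
          out[(R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = TRUE;
      }
    }
  }
  if (bad_columns > 0)
    Rcpp::warning("voxelize: %d degenerate ray column(s) skipped", bad_columns);
  out.attr("dim") = shape;
  return out;
}

// ---------------------------------------------------------------------------
// Squared Euclidean distance transform (distance of every foreground voxel
// centre to the nearest background voxel centre, background including the
// region outside the grid). Felzenszwalb & Huttenlocher lower-envelope
// algorithm, separable, anisotropic spacing.
// ---------------------------------------------------------------------------

static void dt1d(std::vector<double>& f, double s, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z) {
  const int n = (int)f.size();
  const double INF = std::numeric_limits<double>::infinity();
  int k = -1;  // envelope of finite parabolas only
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;
    double qs = q * s;
    if (k < 0) {
      k = 0;
      v[0] = q;
      z[0] = -INF;
      z[1] = INF;
      continue;
    }
    double sint;
    while (true) {
      double vs = v[k] * s;
      sint = ((f[q] + qs * qs) - (f[v[k]] + vs * vs)) / (2.0 * (qs - vs));
      if (sint <= z[k] && k > 0) { --k; } else break;
    }
    if (sint <= z[k] && k == 0) {
      v[0] = q;  // new parabola dominates everywhere
    } else {
      ++k;
      v[k] = q;
      z[k] = sint;
    }
    z[k + 1] = INF;
  }
  if (k < 0) {  // no finite source in this line
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double qs = q * s;
    while (z[k + 1] < qs) ++k;
    double vs = v[k] * s;
    d[q] = (qs - vs) * (qs - vs) + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector shape,
                         NumericVector spacing) {
  const int nx = shape[0], ny = shape[1], nz = shape[2];
  const double INF = std::numeric_limits<double>::infinity();
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = mask[i] ? INF : 0.0;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // x pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      f.assign(g.begin() + base, g.begin() + base + nx);
      dt1d(f, spacing[0], d, v, z);
      for (int i = 0; i < nx; ++i) g[base + i] = d[i];
    }
  // y pass
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j)
        f[j] = g[(R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
      f.resize(ny);
      dt1d(f, spacing[1], d, v, z);
      for (int j = 0; j < ny; ++j)
        g[(R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = d[j];
      f.resize(nmax);
    }
  // z pass
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k)
        f[k] = g[(R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
      f.resize(nz);
      dt1d(f, spacing[2], d, v, z);
      for (int k = 0; k < nz; ++k)
        g[(R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = d[k];
      f.resize(nmax);
    }

  // the region outside the grid is background: cap with the distance to the
  // nearest conceptual outside voxel centre along each axis
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t idx = (R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        if (g[idx] == 0.0) continue;
        double bx = std::min(i + 1, nx - i) * spacing[0];
        double by = std::min(j + 1, ny - j) * spacing[1];
        double bz = std::min(k + 1, nz - k) * spacing[2];
        double b = std::min(bx, std::min(by, bz));
        if (b * b < g[idx]) g[idx] = b * b;
      }
  g.attr("dim") = shape;
  return g;
}

// [[Rcpp::export]]
NumericVector cpp_pair_counts(LogicalVector a, LogicalVector b) {
  R_xlen_t n = a.size();
  double na = 0, nb = 0, ni = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (a[i]) ++na;
    if (b[i]) ++nb;
    if (a[i] && b[i]) ++ni;
  }
  return NumericVector::create(na, nb, ni);
}

// ---------------------------------------------------------------------------
// Nearest-neighbour distances from each point of A to the point set B,
// uniform-grid accelerated with expanding shell search.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_nn_dist(NumericMatrix A, NumericMatrix B, double cell) {
  const int na = A.nrow(), nb = B.nrow();
  NumericVector out(na);
  if (nb == 0) { std::fill(out.begin(), out.end(), NA_REAL); return out; }

  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) { lo[d] = R_PosInf; hi[d] = R_NegInf; }
  for (int p = 0; p < nb; ++p)
    for (int d = 0; d < 3; ++d) {
      lo[d] = std::min(lo[d], B(p, d));
      hi[d] = std::max(hi[d], B(p, d));
    }
  int ng[3];
  for (int d = 0; d < 3; ++d)
    ng[d] = std::max(1, (int)std::floor((hi[d] - lo[d]) / cell) + 1);

  // counting-sort points into cells
  std::vector<int> cidx(nb);
  std::vector<int> count((size_t)ng[0] * ng[1] * ng[2] + 1, 0);
  for (int p = 0; p < nb; ++p) {
    int c[3];
    for (int d = 0; d < 3; ++d) {
      c[d] = (int)std::floor((B(p, d) - lo[d]) / cell);
      c[d] = std::max(0, std::min(ng[d] - 1, c[d]));
    }
    cidx[p] = c[0] + ng[0] * (c[1] + ng[1] * c[2]);
    ++count[cidx[p] + 1];
  }
  for (size_t i = 1; i < count.size(); ++i) count[i] += count[i - 1];
  std::vector<int> order(nb);
  {
    std::vector<int> cur(count.begin(), count.end() - 1);
    for (int p = 0; p < nb; ++p) order[cur[cidx[p]]++] = p;
  }

  const int smax = std::max(ng[0], std::max(ng[1], ng[2]));
  for (int q = 0; q < na; ++q) {
    double px = A(q, 0), py = A(q, 1), pz = A(q, 2);
    int c[3];
    c[0] = (int)std::floor((px - lo[0]) / cell);
    c[1] = (int)std::floor((py - lo[1]) / cell);
    c[2] = (int)std::floor((pz - lo[2]) / cell);
    for (int d = 0; d < 3; ++d) c[d] = std::max(0, std::min(ng[d] - 1, c[d]));
    double best = R_PosInf;  // squared
    for (int s = 0; s <= smax; ++s) {
      // all points in cells at Chebyshev shell s are at least (s-1)*cell away
      if (best < R_PosInf && (double)(s - 1) * cell > std::sqrt(best)) break;
      bool any_cell = false;
      for (int dz = -s; dz <= s; ++dz) {
        int kz = c[2] + dz;
        if (kz < 0 || kz >= ng[2]) continue;
        for (int dy = -s; dy <= s; ++dy) {
          int ky = c[1] + dy;
          if (ky < 0 || ky >= ng[1]) continue;
          bool face_y = (std::abs(dz) == s || std::abs(dy) == s);
          int step = face_y ? 1 : (s == 0 ? 1 : 2 * s);
          for (int dx = -s; dx <= s; dx += (face_y ? 1 : step)) {
            int kx = c[0] + dx;
            if (kx < 0 || kx >= ng[0]) continue;
            any_cell = true;
            int cc = kx + ng[0] * (ky + ng[1] * kz);
            for (int m = count[cc]; m < count[cc + 1]; ++m) {
              int p = order[m];
              double ddx = B(p, 0) - px, ddy = B(p, 1) - py,
                     ddz = B(p, 2) - pz;
              double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
              if (d2 < best) best = d2;
            }
            if (s == 0) break;
          }
        }
      }
      if (!any_cell && best < R_PosInf) break;
    }
    out[q] = std::sqrt(best);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Boundary voxels and boundary (cuberille) surface extraction
// ---------------------------------------------------------------------------

static inline bool mask_at(const LogicalVector& m, int nx, int ny, int nz,
                           int i, int j, int k) {
  if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return false;
  return m[(R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
}

// [[Rcpp::export]]
NumericMatrix cpp_boundary_points(LogicalVector mask, IntegerVector shape,
                                  NumericVector origin, NumericVector spacing) {
  const int nx = shape[0], ny = shape[1], nz = shape[2];
  std::vector<double> pts;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (!mask_at(mask, nx, ny, nz, i, j, k)) continue;
        bool b = !mask_at(mask, nx, ny, nz, i - 1, j, k) ||
                 !mask_at(mask, nx, ny, nz, i + 1, j, k) ||
                 !mask_at(mask, nx, ny, nz, i, j - 1, k) ||
                 !mask_at(mask, nx, ny, nz, i, j + 1, k) ||
                 !mask_at(mask, nx, ny, nz, i, j, k - 1) ||
                 !mask_at(mask, nx, ny, nz, i, j, k + 1);
        if (!b) continue;
        pts.push_back(origin[0] + (i + 0.5) * spacing[0]);
        pts.push_back(origin[1] + (j + 0.5) * spacing[1]);
        pts.push_back(origin[2] + (k + 0.5) * spacing[2]);
      }
  int np = (int)(pts.size() / 3);
  NumericMatrix out(np, 3);
  for (int p = 0; p < np; ++p)
    for (int d = 0; d < 3; ++d) out(p, d) = pts[3 * p + d];
  return out;
}

// [[Rcpp::export]]
List cpp_mask_to_mesh(LogicalVector mask, IntegerVector shape,
                      NumericVector origin, NumericVector spacing) {
  const int nx = shape[0], ny = shape[1], nz = shape[2];
  std::unordered_map<long long, int> vid;
  std::vector<double> verts;   // flat xyz
  std::vector<int> faces;      // flat triples, 0-based

  const long long CX = 1, CY = (long long)(nx + 1),
                  CZ = (long long)(nx + 1) * (ny + 1);
  auto corner = [&](int i, int j, int k) -> int {
    long long key = CX * i + CY * j + CZ * k;
    auto it = vid.find(key);
    if (it != vid.end()) return it->second;
    int id = (int)(verts.size() / 3);
    vid.emplace(key, id);
    verts.push_back(origin[0] + i * spacing[0]);
    verts.push_back(origin[1] + j * spacing[1]);
    verts.push_back(origin[2] + k * spacing[2]);
    return id;
  };
  auto quad = [&](int a, int b, int c, int d) {
    faces.push_back(a); faces.push_back(b); faces.push_back(c);
    faces.push_back(a); faces.push_back(c); faces.push_back(d);
  };

  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (!mask_at(mask, nx, ny, nz, i, j, k)) continue;
        if (!mask_at(mask, nx, ny, nz, i + 1, j, k))  // +x
          quad(corner(i + 1, j, k), corner(i + 1, j + 1, k),
               corner(i + 1, j + 1, k + 1), corner(i + 1, j, k + 1));
        if (!mask_at(mask, nx, ny, nz, i - 1, j, k))  // -x
          quad(corner(i, j, k), corner(i, j, k + 1),
               corner(i, j + 1, k + 1), corner(i, j + 1, k));
        if (!mask_at(mask, nx, ny, nz, i, j + 1, k))  // +y
          quad(corner(i, j + 1, k), corner(i, j + 1, k + 1),
               corner(i + 1, j + 1, k + 1), corner(i + 1, j + 1, k));
        if (!mask_at(mask, nx, ny, nz, i, j - 1, k))  // -y
          quad(corner(i, j, k), corner(i + 1, j, k),
               corner(i + 1, j, k + 1), corner(i, j, k + 1));
        if (!mask_at(mask, nx, ny, nz, i, j, k + 1))  // +z
          quad(corner(i, j, k + 1), corner(i + 1, j, k + 1),
               corner(i + 1, j + 1, k + 1), corner(i, j + 1, k + 1));
        if (!mask_at(mask, nx, ny, nz, i, j, k - 1))  // -z
          quad(corner(i, j, k), corner(i, j + 1, k),
               corner(i + 1, j + 1, k), corner(i + 1, j, k));
      }

  int nv = (int)(verts.size() / 3), nf = (int)(faces.size() / 3);
  NumericMatrix Vm(nv, 3);
  for (int p = 0; p < nv; ++p)
    for (int d = 0; d < 3; ++d) Vm(p, d) = verts[3 * p + d];
  IntegerMatrix Fm(nf, 3);
  for (int p = 0; p < nf; ++p)
    for (int d = 0; d < 3; ++d) Fm(p, d) = faces[3 * p + d] + 1;  // 1-based
  return List::create(_["vertices"] = Vm, _["faces"] = Fm);
}

// ---------------------------------------------------------------------------
// Exact point-to-triangle-mesh distances (min over faces of the distance to
// the closest point on each triangle)
// ---------------------------------------------------------------------------

static double point_tri_dist2(const double* p, const double* a,
                              const double* b, const double* c) {
  double ab[3], ac[3], ap[3];
  for (int d = 0; d < 3; ++d) {
    ab[d] = b[d] - a[d]; ac[d] = c[d] - a[d]; ap[d] = p[d] - a[d];
  }
  double d1 = dot3(ab, ap), d2 = dot3(ac, ap);
  double px[3];
  if (d1 <= 0.0 && d2 <= 0.0) { for (int d = 0; d < 3; ++d) px[d] = a[d]; }
  else {
    double bp[3], cp[3];
    for (int d = 0; d < 3; ++d) { bp[d] = p[d] - b[d]; cp[d] = p[d] - c[d]; }
    double d3 = dot3(ab, bp), d4 = dot3(ac, bp);
    double d5 = dot3(ab, cp), d6 = dot3(ac, cp);
    if (d3 >= 0.0 && d4 <= d3) { for (int d = 0; d < 3; ++d) px[d] = b[d]; }
    else if (d6 >= 0.0 && d5 <= d6) { for (int d = 0; d < 3; ++d) px[d] = c[d]; }
    else {
      double vc = d1 * d4 - d3 * d2;
      if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
        double v = d1 / (d1 - d3);
        for (int d = 0; d < 3; ++d) px[d] = a[d] + v * ab[d];
      } else {
        double vb = d5 * d2 - d1 * d6;
        if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
          double w = d2 / (d2 - d6);
          for (int d = 0; d < 3; ++d) px[d] = a[d] + w * ac[d];
        } else {
          double va = d3 * d6 - d5 * d4;
          if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
            double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
            for (int d = 0; d < 3; ++d) px[d] = b[d] + w * (c[d] - b[d]);
          } else {
            double denom = 1.0 / (va + vb + vc);
            double v = vb * denom, w = vc * denom;
            for (int d = 0; d < 3; ++d) px[d] = a[d] + v * ab[d] + w * ac[d];
          }
        }
      }
    }
  }
  double s = 0.0;
  for (int d = 0; d < 3; ++d) { double t = p[d] - px[d]; s += t * t; }
  return s;
}

// [[Rcpp::export]]
NumericVector cpp_point_mesh_dist(NumericMatrix P, NumericMatrix V,
                                  IntegerMatrix F) {
  const int np = P.nrow(), nf = F.nrow();
  NumericVector out(np);
  for (int q = 0; q < np; ++q) {
    double p[3] = {P(q, 0), P(q, 1), P(q, 2)};
    double best = R_PosInf;
    for (int t = 0; t < nf; ++t) {
      double a[3] = {V(F(t, 0), 0), V(F(t, 0), 1), V(F(t, 0), 2)};
      double b[3] = {V(F(t, 1), 0), V(F(t, 1), 1), V(F(t, 1), 2)};
      double c[3] = {V(F(t, 2), 0), V(F(t, 2), 1), V(F(t, 2), 2)};
      double d2 = point_tri_dist2(p, a, b, c);
      if (d2 < best) best = d2;
    }
    out[q] = std::sqrt(best);
  }
  return out;
}
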