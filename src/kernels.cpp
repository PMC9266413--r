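#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Exact k-nearest-neighbour search, brute force. Ties broken by lower
// reference index: candidates are ordered by (distance, index).
// [[Rcpp::export]]
List cpp_knn(NumericMatrix query, NumericMatrix ref, int k) {
  const int m = query.nrow(), n = ref.nrow();
  if (k < 1) stop("k must be >= 1");
  if (k > n) stop("k (%d) exceeds the number of reference points (%d)", k, n);
  IntegerMatrix idx(m, k);
  NumericMatrix dst(m, k);
  std::vector<std::pair<double, int> > cand(n);
  for (int q = 0; q < m; ++q) {
    const double qx = query(q, 0), qy = query(q, 1), qz = query(q, 2);
    for (int r = 0; r < n; ++r) {
      const double dx = ref(r, 0) - qx, dy = ref(r, 1) - qy, dz = ref(r, 2) - qz;
      cand[r] = std::make_pair(dx * dx + dy * dy + dz * dz, r);
    }
    std::partial_sort(cand.begin(), cand.begin() + k, cand.end());
    for (int j = 0; j < k; ++j) {
      idx(q, j) = cand[j].second + 1;
      dst(q, j) = std::sqrt(cand[j].first);
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dst);
}

// All (query, ref) pairs with distance <= radius, as a 1-based edge list
// ordered by query index then reference index. exclude_self drops i == j
// pairs (meaningful only when query and ref are the same array).
// [[Rcpp::export]]
List cpp_radius_edges(NumericMatrix query, NumericMatrix ref, double radius,
                      bool exclude_self) {
  const int m = query.nrow(), n = ref.nrow();
  if (radius <= 0) stop("radius must be positive");
  const double r2 = radius * radius;
  std::vector<int> ii, jj;
  std::vector<double> dd;
  for (int q = 0; q < m; ++q) {
    const double qx = query(q, 0), qy = query(q, 1), qz = query(q, 2);
    for (int r = 0; r < n; ++r) {
      if (exclude_self && q == r) continue;
      const double dx = ref(r, 0) - qx, dy = ref(r, 1) - qy, dz = ref(r, 2) - qz;
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 <= r2) {
        ii.push_back(q + 1);
        jj.push_back(r + 1);
        dd.push_back(std::sqrt(d2));
      }
    }
  }
  return List::create(_["i"] = wrap(ii), _["j"] = wrap(jj), _["dist"] = wrap(dd));
}

// Signed Euclidean distance field on a regular grid:
// f(g) = min_i (|g - p_i| - r_i) - probe.
// Exact at every grid point (the inner loop prunes sqrt calls with the
// current best bound; the result is identical to the naive evaluation).
// [[Rcpp::export]]
NumericVector cpp_distance_field(NumericMatrix atoms, NumericVector radii,
                                 NumericVector origin, double spacing,
                                 IntegerVector dims, double probe) {
  const int n = atoms.nrow();
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  double rmax = 0.0;
  for (int i = 0; i < n; ++i) rmax = std::max(rmax, radii[i]);
  R_xlen_t p = 0;
  for (int iz = 0; iz < nz; ++iz) {
    const double gz = origin[2] + spacing * iz;
    for (int iy = 0; iy < ny; ++iy) {
      const double gy = origin[1] + spacing * iy;
      for (int ix = 0; ix < nx; ++ix, ++p) {
        const double gx = origin[0] + spacing * ix;
        double best = R_PosInf;
        double thresh2 = R_PosInf;
        for (int i = 0; i < n; ++i) {
          const double dx = atoms(i, 0) - gx, dy = atoms(i, 1) - gy,
                       dz = atoms(i, 2) - gz;
          const double d2 = dx * dx + dy * dy + dz * dz;
          if (d2 < thresh2) {
            const double v = std::sqrt(d2) - radii[i];
            if (v < best) {
              best = v;
              const double t = best + rmax;
              thresh2 = (t > 0) ? t * t : 0.0;
            }
          }
        }
        out[p] = best - probe;
      }
    }
  }
  return out;
}

// Banded variant: values are exact wherever |f| < band and clamped to +band
// elsewhere (every grid point inside the inflated envelope, or within `band`
// outside of it, lies within r_i + probe + band of its minimising atom, so a
// per-atom local sweep reproduces the exact minimum there; the field is
// 1-Lipschitz, so no level-set cell can straddle unvisited points).
// [[Rcpp::export]]
NumericVector cpp_distance_field_banded(NumericMatrix atoms, NumericVector radii,
                                        NumericVector origin, double spacing,
                                        IntegerVector dims, double probe,
                                        double band) {
  const int n = atoms.nrow();
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out((R_xlen_t)nx * ny * nz, band);
  for (int i = 0; i < n; ++i) {
    const double ax = atoms(i, 0), ay = atoms(i, 1), az = atoms(i, 2);
    const double rcut = radii[i] + probe + band;
    const int x0 = std::max(0, (int)std::ceil((ax - rcut - origin[0]) / spacing));
    const int x1 = std::min(nx - 1, (int)std::floor((ax + rcut - origin[0]) / spacing));
    const int y0 = std::max(0, (int)std::ceil((ay - rcut - origin[1]) / spacing));
    const int y1 = std::min(ny - 1, (int)std::floor((ay + rcut - origin[1]) / spacing));
    const int z0 = std::max(0, (int)std::ceil((az - rcut - origin[2]) / spacing));
    const int z1 = std::min(nz - 1, (int)std::floor((az + rcut - origin[2]) / spacing));
    for (int iz = z0; iz <= z1; ++iz) {
      const double dz = origin[2] + spacing * iz - az;
      for (int iy = y0; iy <= y1; ++iy) {
        const double dy = origin[1] + spacing * iy - ay;
        const double d2yz = dy * dy + dz * dz;
        R_xlen_t base = (R_xlen_t)nx * ((R_xlen_t)iy + (R_xlen_t)ny * iz);
        for (int ix = x0; ix <= x1; ++ix) {
          const double dx = origin[0] + spacing * ix - ax;
          const double v = std::sqrt(dx * dx + d2yz) - radii[i] - probe;
          if (v < out[base + ix]) out[base + ix] = v;
        }
      }
    }
  }
  return out;
}

// Marching tetrahedra on a regular grid (Freudenthal 6-tet cube split, so
// shared cube faces are diagonalised consistently and the mesh is closed
// whenever the level set stays off the grid boundary). Edge-interpolated
// vertices are welded through a map keyed by the global indices of the two
// grid endpoints. Triangles are wound so the right-hand normal points toward
// increasing field values.
// [[Rcpp::export]]
List cpp_marching_tets(NumericVector field, IntegerVector dims,
                       NumericVector origin, double spacing, double level) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t ngrid = (R_xlen_t)nx * ny * nz;
  std::vector<double> f(ngrid);
  bool straddles_lo = false, straddles_hi = false;
  for (R_xlen_t i = 0; i < ngrid; ++i) {
    double v = field[i] - level;
    if (std::fabs(v) < 1e-12) v = 1e-12;  // avoid degenerate on-grid crossings
    f[i] = v;
    if (v < 0) straddles_lo = true; else straddles_hi = true;
  }
  if (!straddles_lo || !straddles_hi)
    stop("isosurface level lies outside the range of the field");

  // the six tetrahedra per cube: paths from corner (0,0,0) to (1,1,1)
  static const int perms[6][3] = {{0, 1, 2}, {0, 2, 1}, {1, 0, 2},
                                  {1, 2, 0}, {2, 0, 1}, {2, 1, 0}};
  std::unordered_map<uint64_t, int> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> fa, fb, fc;

  auto gidx = [&](int ix, int iy, int iz) -> R_xlen_t {
    return (R_xlen_t)ix + (R_xlen_t)nx * ((R_xlen_t)iy + (R_xlen_t)ny * iz);
  };
  auto gpos = [&](R_xlen_t g, double *p) {
    const int ix = (int)(g % nx);
    const int iy = (int)((g / nx) % ny);
    const int iz = (int)(g / ((R_xlen_t)nx * ny));
    p[0] = origin[0] + spacing * ix;
    p[1] = origin[1] + spacing * iy;
    p[2] = origin[2] + spacing * iz;
  };
  auto edge_point = [&](R_xlen_t ga, R_xlen_t gb) -> int {
    const uint64_t a = (uint64_t)std::min(ga, gb), b = (uint64_t)std::max(ga, gb);
    const uint64_t key = a * (uint64_t)ngrid + b;
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    double pa[3], pb[3];
    gpos(ga, pa);
    gpos(gb, pb);
    const double va = f[ga], vb = f[gb];
    const double t = va / (va - vb);
    const int id = (int)vx.size();
    vx.push_back(pa[0] + t * (pb[0] - pa[0]));
    vy.push_back(pa[1] + t * (pb[1] - pa[1]));
    vz.push_back(pa[2] + t * (pb[2] - pa[2]));
    edge_vertex[key] = id;
    return id;
  };
  auto add_tri = [&](int a, int b, int c, const double *inside_c,
                     const double *outside_c) {
    // orient: normal of (a,b,c) should point from inside (f<0) to outside
    const double ux = vx[b] - vx[a], uy = vy[b] - vy[a], uz = vz[b] - vz[a];
    const double wx = vx[c] - vx[a], wy = vy[c] - vy[a], wz = vz[c] - vz[a];
    const double nxv = uy * wz - uz * wy;
    const double nyv = uz * wx - ux * wz;
    const double nzv = ux * wy - uy * wx;
    const double dx = outside_c[0] - inside_c[0];
    const double dy = outside_c[1] - inside_c[1];
    const double dz = outside_c[2] - inside_c[2];
    if (nxv * dx + nyv * dy + nzv * dz >= 0) {
      fa.push_back(a + 1); fb.push_back(b + 1); fc.push_back(c + 1);
    } else {
      fa.push_back(a + 1); fb.push_back(c + 1); fc.push_back(b + 1);
    }
  };

  R_xlen_t corners[4];
  for (int iz = 0; iz + 1 < nz; ++iz) {
    for (int iy = 0; iy + 1 < ny; ++iy) {
      for (int ix = 0; ix + 1 < nx; ++ix) {
        for (int t = 0; t < 6; ++t) {
          int c[3] = {ix, iy, iz};
          corners[0] = gidx(c[0], c[1], c[2]);
          c[perms[t][0]]++;
          corners[1] = gidx(c[0], c[1], c[2]);
          c[perms[t][1]]++;
          corners[2] = gidx(c[0], c[1], c[2]);
          corners[3] = gidx(ix + 1, iy + 1, iz + 1);

          int inside[4], nin = 0, nout = 0, outside[4];
          for (int q = 0; q < 4; ++q) {
            if (f[corners[q]] < 0) inside[nin++] = q; else outside[nout++] = q;
          }
          if (nin == 0 || nin == 4) continue;

          double cin[3] = {0, 0, 0}, cout[3] = {0, 0, 0}, pp[3];
          for (int q = 0; q < nin; ++q) {
            gpos(corners[inside[q]], pp);
            cin[0] += pp[0] / nin; cin[1] += pp[1] / nin; cin[2] += pp[2] / nin;
          }
          for (int q = 0; q < nout; ++q) {
            gpos(corners[outside[q]], pp);
            cout[0] += pp[0] / nout; cout[1] += pp[1] / nout; cout[2] += pp[2] / nout;
          }

          if (nin == 1) {
            const R_xlen_t A = corners[inside[0]];
            const int e0 = edge_point(A, corners[outside[0]]);
            const int e1 = edge_point(A, corners[outside[1]]);
            const int e2 = edge_point(A, corners[outside[2]]);
            add_tri(e0, e1, e2, cin, cout);
          } else if (nin == 3) {
            const R_xlen_t A = corners[outside[0]];
            const int e0 = edge_point(A, corners[inside[0]]);
            const int e1 = edge_point(A, corners[inside[1]]);
            const int e2 = edge_point(A, corners[inside[2]]);
            add_tri(e0, e1, e2, cin, cout);
          } else {  // 2 in, 2 out -> quad split into two triangles
            const R_xlen_t A = corners[inside[0]], B = corners[inside[1]];
            const R_xlen_t C = corners[outside[0]], D = corners[outside[1]];
            const int ac = edge_point(A, C), ad = edge_point(A, D);
            const int bc = edge_point(B, C), bd = edge_point(B, D);
            add_tri(ac, ad, bd, cin, cout);
            add_tri(ac, bd, bc, cin, cout);
          }
        }
      }
    }
  }

  const int nv = (int)vx.size();
  NumericMatrix verts(nv, 3);
  for (int i = 0; i < nv; ++i) {
    verts(i, 0) = vx[i]; verts(i, 1) = vy[i]; verts(i, 2) = vz[i];
  }
  const int nf = (int)fa.size();
  IntegerMatrix faces(nf, 3);
  for (int i = 0; i < nf; ++i) {
    faces(i, 0) = fa[i]; faces(i, 1) = fb[i]; faces(i, 2) = fc[i];
  }
  return List::create(_["vertices"] = verts, _["faces"] = faces);
}

// For each query point, is any reference point within `cutoff`? Cell-list
// accelerated (cell size = cutoff, 27-cell stencil), exact for <= cutoff.
// [[Rcpp::export]]
LogicalVector cpp_within_dist(NumericMatrix query, NumericMatrix ref,
                              double cutoff) {
  const int m = query.nrow(), n = ref.nrow();
  if (cutoff <= 0) stop("cutoff must be positive");
  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) { lo[d] = R_PosInf; hi[d] = R_NegInf; }
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      lo[d] = std::min(lo[d], ref(i, d));
      hi[d] = std::max(hi[d], ref(i, d));
    }
  const double cs = cutoff;
  int nc[3];
  for (int d = 0; d < 3; ++d)
    nc[d] = std::max(1, (int)std::floor((hi[d] - lo[d]) / cs) + 1);
  auto cell_of = [&](double x, int d) {
    int c = (int)std::floor((x - lo[d]) / cs);
    return std::min(std::max(c, 0), nc[d] - 1);
  };
  std::unordered_map<int64_t, std::vector<int> > cells;
  for (int i = 0; i < n; ++i) {
    const int64_t key =
        cell_of(ref(i, 0), 0) +
        (int64_t)nc[0] * (cell_of(ref(i, 1), 1) +
                          (int64_t)nc[1] * cell_of(ref(i, 2), 2));
    cells[key].push_back(i);
  }
  LogicalVector out(m);
  const double c2 = cutoff * cutoff;
  for (int q = 0; q < m; ++q) {
    const double qx = query(q, 0), qy = query(q, 1), qz = query(q, 2);
    const int cx = cell_of(qx, 0), cy = cell_of(qy, 1), cz = cell_of(qz, 2);
    bool hit = false;
    // the query may fall outside the ref bounding box; clamped cells plus a
    // bound check keep the result exact
    if (qx > hi[0] + cutoff || qx < lo[0] - cutoff ||
        qy > hi[1] + cutoff || qy < lo[1] - cutoff ||
        qz > hi[2] + cutoff || qz < lo[2] - cutoff) {
      out[q] = false;
      continue;
    }
    for (int dz = -1; dz <= 1 && !hit; ++dz) {
      const int z = cz + dz;
      if (z < 0 || z >= nc[2]) continue;
      for (int dy = -1; dy <= 1 && !hit; ++dy) {
        const int y = cy + dy;
        if (y < 0 || y >= nc[1]) continue;
        for (int dx = -1; dx <= 1 && !hit; ++dx) {
          const int x = cx + dx;
          if (x < 0 || x >= nc[0]) continue;
          auto it = cells.find(x + (int64_t)nc[0] * (y + (int64_t)nc[1] * z));
          if (it == cells.end()) continue;
          for (int i : it->second) {
            const double ddx = ref(i, 0) - qx, ddy = ref(i, 1) - qy,
                         ddz = ref(i, 2) - qz;
            if (ddx * ddx + ddy * ddy + ddz * ddz <= c2) { hit = true; break; }
          }
        }
      }
    }
    out[q] = hit;
  }
  return out;
}
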