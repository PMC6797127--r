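// Voxel geometry engine: mesh rasterization, isosurface extraction,
// occupancy Booleans and supporting queries. All distances in mm.
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// Rasterize a closed triangle mesh to an occupancy grid by parity counting of
// z-ray crossings at voxel-column centers. Columns whose ray grazes an edge or
// vertex are resolved by the caller jittering the grid origin off any lattice
// the mesh may be aligned with; residual odd-parity columns drop their last
// crossing (returned in attribute "odd_columns" for diagnostics).
// [[Rcpp::export]]
RawVector voxelize_mesh_cpp(NumericMatrix V, IntegerMatrix F,
                            NumericVector origin, double pitch,
                            IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const int nf = F.nrow();
  std::vector<std::vector<float> > cross((size_t)nx * ny);

  for (int t = 0; t < nf; ++t) {
    const int a = F(t, 0), b = F(t, 1), c = F(t, 2);
    const double x0 = V(a, 0), y0 = V(a, 1), z0 = V(a, 2);
    const double x1 = V(b, 0), y1 = V(b, 1), z1 = V(b, 2);
    const double x2 = V(c, 0), y2 = V(c, 1), z2 = V(c, 2);
    const double xmn = std::min(x0, std::min(x1, x2));
    const double xmx = std::max(x0, std::max(x1, x2));
    const double ymn = std::min(y0, std::min(y1, y2));
    const double ymx = std::max(y0, std::max(y1, y2));
    int i0 = (int)std::ceil((xmn - ox) / pitch - 0.5);
    int i1 = (int)std::floor((xmx - ox) / pitch - 0.5);
    int j0 = (int)std::ceil((ymn - oy) / pitch - 0.5);
    int j1 = (int)std::floor((ymx - oy) / pitch - 0.5);
    if (i0 < 0) i0 = 0;
    if (j0 < 0) j0 = 0;
    if (i1 >= nx) i1 = nx - 1;
    if (j1 >= ny) j1 = ny - 1;
    for (int j = j0; j <= j1; ++j) {
      const double cy = oy + (j + 0.5) * pitch;
      for (int i = i0; i <= i1; ++i) {
        const double cx = ox + (i + 0.5) * pitch;
        const double l0 = (x1 - cx) * (y2 - cy) - (x2 - cx) * (y1 - cy);
        const double l1 = (x2 - cx) * (y0 - cy) - (x0 - cx) * (y2 - cy);
        const double l2 = (x0 - cx) * (y1 - cy) - (x1 - cx) * (y0 - cy);
        const double s = l0 + l1 + l2;
        if (std::fabs(s) < 1e-12) continue;  // degenerate / z-parallel
        const bool pos = l0 > 0 && l1 > 0 && l2 > 0;
        const bool neg = l0 < 0 && l1 < 0 && l2 < 0;
        if (!pos && !neg) continue;
        const double z = (l0 * z0 + l1 * z1 + l2 * z2) / s;
        cross[(size_t)j * nx + i].push_back((float)z);
      }
    }
  }

  RawVector occ((size_t)nx * ny * nz);  // zero-initialized
  int odd = 0;
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      std::vector<float> &v = cross[(size_t)j * nx + i];
      if (v.empty()) continue;
      std::sort(v.begin(), v.end());
      size_t m = v.size();
      if (m & 1) {
        ++odd;
        --m;
      }
      for (size_t k = 0; k < m; k += 2) {
        const double zlo = v[k], zhi = v[k + 1];
        int k0 = (int)std::ceil((zlo - oz) / pitch - 0.5);
        int k1 = (int)std::floor((zhi - oz) / pitch - 0.5);
        if (k0 < 0) k0 = 0;
        if (k1 >= nz) k1 = nz - 1;
        for (int kk = k0; kk <= k1; ++kk)
          occ[((size_t)kk * ny + j) * nx + i] = 1;
      }
    }
  }
  occ.attr("odd_columns") = odd;
  return occ;
}

// Element-wise occupancy Boolean: op 1 = difference (a & !b),
// 2 = intersection, 3 = union.
// [[Rcpp::export]]
RawVector occ_op_cpp(RawVector a, RawVector b, int op) {
  const R_xlen_t n = a.size();
  if (b.size() != n) stop("occupancy grids differ in size");
  RawVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const bool x = a[i] != 0, y = b[i] != 0;
    bool r = false;
    if (op == 1)
      r = x && !y;
    else if (op == 2)
      r = x && y;
    else
      r = x || y;
    out[i] = r ? 1 : 0;
  }
  return out;
}

// Extract the boundary of an occupancy grid as a watertight, consistently
// outward-oriented triangle mesh of voxel faces. Enclosed volume equals
// (number of occupied voxels) * pitch^3 exactly.
// [[Rcpp::export]]
List cuberille_cpp(RawVector occ, IntegerVector dims, NumericVector origin,
                   double pitch) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int64_t mx = nx + 1, my = ny + 1;
  std::unordered_map<int64_t, int> nodes;
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;

  auto node = [&](int i, int j, int k) -> int {
    const int64_t key = i + mx * (j + my * (int64_t)k);
    auto it = nodes.find(key);
    if (it != nodes.end()) return it->second;
    const int id = (int)vx.size();
    nodes.emplace(key, id);
    vx.push_back(origin[0] + i * pitch);
    vy.push_back(origin[1] + j * pitch);
    vz.push_back(origin[2] + k * pitch);
    return id;
  };
  auto occupied = [&](int i, int j, int k) -> bool {
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return false;
    return occ[((size_t)k * ny + j) * nx + i] != 0;
  };
  auto quad = [&](int a, int b, int c, int d) {
    tri.push_back(a); tri.push_back(b); tri.push_back(c);
    tri.push_back(a); tri.push_back(c); tri.push_back(d);
  };

  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (!occupied(i, j, k)) continue;
        // +x / -x
        if (!occupied(i + 1, j, k))
          quad(node(i + 1, j, k), node(i + 1, j + 1, k),
               node(i + 1, j + 1, k + 1), node(i + 1, j, k + 1));
        if (!occupied(i - 1, j, k))
          quad(node(i, j, k), node(i, j, k + 1), node(i, j + 1, k + 1),
               node(i, j + 1, k));
        // +y / -y
        if (!occupied(i, j + 1, k))
          quad(node(i, j + 1, k), node(i, j + 1, k + 1),
               node(i + 1, j + 1, k + 1), node(i + 1, j + 1, k));
        if (!occupied(i, j - 1, k))
          quad(node(i, j, k), node(i + 1, j, k), node(i + 1, j, k + 1),
               node(i, j, k + 1));
        // +z / -z
        if (!occupied(i, j, k + 1))
          quad(node(i, j, k + 1), node(i + 1, j, k + 1),
               node(i + 1, j + 1, k + 1), node(i, j + 1, k + 1));
        if (!occupied(i, j, k - 1))
          quad(node(i, j, k), node(i, j + 1, k), node(i + 1, j + 1, k),
               node(i + 1, j, k));
      }

  const int nv = (int)vx.size(), nt = (int)tri.size() / 3;
  NumericMatrix Vm(nv, 3);
  for (int i = 0; i < nv; ++i) {
    Vm(i, 0) = vx[i]; Vm(i, 1) = vy[i]; Vm(i, 2) = vz[i];
  }
  IntegerMatrix Fm(nt, 3);
  for (int t = 0; t < nt; ++t) {
    Fm(t, 0) = tri[3 * t] + 1;
    Fm(t, 1) = tri[3 * t + 1] + 1;
    Fm(t, 2) = tri[3 * t + 2] + 1;
  }
  return List::create(_["vertices"] = Vm, _["faces"] = Fm);
}

// Marching tetrahedra over a scalar field sampled at grid nodes (column-major
// array of dimension ndim). Inside is field < iso. Uses the Kuhn 6-tetrahedra
// cube subdivision, which is face-consistent between neighboring cubes, so the
// result is watertight. Triangles are oriented outward (inside -> outside).
// [[Rcpp::export]]
List marching_tets_cpp(NumericVector field, IntegerVector ndim,
                       NumericVector origin, double pitch, double iso) {
  const int nnx = ndim[0], nny = ndim[1], nnz = ndim[2];
  const int64_t NN = (int64_t)nnx * nny * nnz;
  static const int perms[6][3] = {{0, 1, 2}, {0, 2, 1}, {1, 0, 2},
                                  {1, 2, 0}, {2, 0, 1}, {2, 1, 0}};
  std::unordered_map<uint64_t, int> everts;
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;

  // node values exactly on the iso level would create degenerate (zero-area)
  // triangles with ambiguous orientation; nudge them consistently per node
  auto fval = [&](int64_t id) -> double {
    const double f = field[id];
    return f == iso ? iso + 1e-9 : f;
  };
  auto nid = [&](int i, int j, int k) -> int64_t {
    return i + (int64_t)nnx * (j + (int64_t)nny * k);
  };
  auto ncoord = [&](int64_t id, double *p) {
    const int i = (int)(id % nnx);
    const int j = (int)((id / nnx) % nny);
    const int k = (int)(id / ((int64_t)nnx * nny));
    p[0] = origin[0] + i * pitch;
    p[1] = origin[1] + j * pitch;
    p[2] = origin[2] + k * pitch;
  };
  // interpolated vertex on edge (a,b), deduplicated by node-id pair
  auto evert = [&](int64_t a, int64_t b) -> int {
    int64_t lo = a < b ? a : b, hi = a < b ? b : a;
    const uint64_t key = (uint64_t)lo * (uint64_t)NN + (uint64_t)hi;
    auto it = everts.find(key);
    if (it != everts.end()) return it->second;
    double pa[3], pb[3];
    ncoord(a, pa);
    ncoord(b, pb);
    const double fa = fval(a), fb = fval(b);
    double t = (iso - fa) / (fb - fa);
    if (t < 0) t = 0;
    if (t > 1) t = 1;
    const int id = (int)vx.size();
    everts.emplace(key, id);
    vx.push_back(pa[0] + t * (pb[0] - pa[0]));
    vy.push_back(pa[1] + t * (pb[1] - pa[1]));
    vz.push_back(pa[2] + t * (pb[2] - pa[2]));
    return id;
  };
  auto emit = [&](int v0, int v1, int v2, const double *dir) {
    // orient so normal points from inside toward outside (along dir)
    const double ux = vx[v1] - vx[v0], uy = vy[v1] - vy[v0],
                 uz = vz[v1] - vz[v0];
    const double wx2 = vx[v2] - vx[v0], wy2 = vy[v2] - vy[v0],
                 wz2 = vz[v2] - vz[v0];
    const double nxv = uy * wz2 - uz * wy2;
    const double nyv = uz * wx2 - ux * wz2;
    const double nzv = ux * wy2 - uy * wx2;
    if (nxv * dir[0] + nyv * dir[1] + nzv * dir[2] < 0) std::swap(v1, v2);
    tri.push_back(v0); tri.push_back(v1); tri.push_back(v2);
  };

  int64_t tn[4];
  for (int k = 0; k + 1 < nnz; ++k)
    for (int j = 0; j + 1 < nny; ++j)
      for (int i = 0; i + 1 < nnx; ++i) {
        // quick reject: all 8 corners on the same side
        bool anyin = false, anyout = false;
        for (int d = 0; d < 8; ++d) {
          const double f =
              fval(nid(i + (d & 1), j + ((d >> 1) & 1), k + ((d >> 2) & 1)));
          if (f < iso) anyin = true; else anyout = true;
        }
        if (!anyin || !anyout) continue;
        for (int p = 0; p < 6; ++p) {
          int ci = i, cj = j, ck = k;
          tn[0] = nid(ci, cj, ck);
          for (int step = 0; step < 2; ++step) {
            const int ax = perms[p][step];
            if (ax == 0) ++ci; else if (ax == 1) ++cj; else ++ck;
            tn[step + 1] = nid(ci, cj, ck);
          }
          tn[3] = nid(i + 1, j + 1, k + 1);
          bool in[4];
          int cnt = 0;
          for (int d = 0; d < 4; ++d) {
            in[d] = fval(tn[d]) < iso;
            if (in[d]) ++cnt;
          }
          if (cnt == 0 || cnt == 4) continue;
          // inside->outside direction for orientation
          double cin[3] = {0, 0, 0}, cout[3] = {0, 0, 0}, pc[3];
          for (int d = 0; d < 4; ++d) {
            ncoord(tn[d], pc);
            double *acc = in[d] ? cin : cout;
            acc[0] += pc[0]; acc[1] += pc[1]; acc[2] += pc[2];
          }
          const int no = 4 - cnt;
          double dir[3] = {cout[0] / no - cin[0] / cnt,
                           cout[1] / no - cin[1] / cnt,
                           cout[2] / no - cin[2] / cnt};
          int ins[4], outs[4];
          int ni = 0, no2 = 0;
          for (int d = 0; d < 4; ++d) {
            if (in[d]) ins[ni++] = d; else outs[no2++] = d;
          }
          if (cnt == 1) {
            const int A = ins[0];
            emit(evert(tn[A], tn[outs[0]]), evert(tn[A], tn[outs[1]]),
                 evert(tn[A], tn[outs[2]]), dir);
          } else if (cnt == 3) {
            const int D = outs[0];
            emit(evert(tn[ins[0]], tn[D]), evert(tn[ins[1]], tn[D]),
                 evert(tn[ins[2]], tn[D]), dir);
          } else {
            const int A = ins[0], B = ins[1], C = outs[0], D = outs[1];
            const int q0 = evert(tn[A], tn[C]);
            const int q1 = evert(tn[A], tn[D]);
            const int q2 = evert(tn[B], tn[D]);
            const int q3 = evert(tn[B], tn[C]);
            emit(q0, q1, q2, dir);
            emit(q0, q2, q3, dir);
          }
        }
      }

  const int nv = (int)vx.size(), nt = (int)tri.size() / 3;
  NumericMatrix Vm(nv, 3);
  for (int v = 0; v < nv; ++v) {
    Vm(v, 0) = vx[v]; Vm(v, 1) = vy[v]; Vm(v, 2) = vz[v];
  }
  IntegerMatrix Fm(nt, 3);
  for (int t = 0; t < nt; ++t) {
    Fm(t, 0) = tri[3 * t] + 1;
    Fm(t, 1) = tri[3 * t + 1] + 1;
    Fm(t, 2) = tri[3 * t + 2] + 1;
  }
  return List::create(_["vertices"] = Vm, _["faces"] = Fm);
}

// 6-connected component labelling of an occupancy grid; labels 1..K, 0 empty.
// [[Rcpp::export]]
IntegerVector label_components_cpp(RawVector occ, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t n = (size_t)nx * ny * nz;
  IntegerVector lab(n);  // zero-initialized
  std::vector<size_t> stack;
  int next = 0;
  for (size_t s = 0; s < n; ++s) {
    if (occ[s] == 0 || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      const size_t cur = stack.back();
      stack.pop_back();
      const int i = (int)(cur % nx);
      const int j = (int)((cur / nx) % ny);
      const int k = (int)(cur / ((size_t)nx * ny));
      const int di[6] = {1, -1, 0, 0, 0, 0};
      const int dj[6] = {0, 0, 1, -1, 0, 0};
      const int dk[6] = {0, 0, 0, 0, 1, -1};
      for (int d = 0; d < 6; ++d) {
        const int ii = i + di[d], jj = j + dj[d], kk = k + dk[d];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
          continue;
        const size_t t = ((size_t)kk * ny + jj) * nx + ii;
        if (occ[t] != 0 && lab[t] == 0) {
          lab[t] = next;
          stack.push_back(t);
        }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}

// Zero out voxels whose component label is not kept. keep is indexed by label
// (length = number of components).
// [[Rcpp::export]]
RawVector keep_components_cpp(IntegerVector lab, LogicalVector keep) {
  const R_xlen_t n = lab.size();
  RawVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const int l = lab[i];
    out[i] = (l > 0 && keep[l - 1]) ? 1 : 0;
  }
  return out;
}

static inline void sector_basis(const double *n, const double *zax,
                                const double *yax, double *u1, double *u2) {
  // in-plane cranial reference u1 and anterior reference u2 = u1 x n,
  // flipped if needed to point anterior
  double d = zax[0] * n[0] + zax[1] * n[1] + zax[2] * n[2];
  u1[0] = zax[0] - d * n[0];
  u1[1] = zax[1] - d * n[1];
  u1[2] = zax[2] - d * n[2];
  double l = std::sqrt(u1[0] * u1[0] + u1[1] * u1[1] + u1[2] * u1[2]);
  u1[0] /= l; u1[1] /= l; u1[2] /= l;
  u2[0] = u1[1] * n[2] - u1[2] * n[1];
  u2[1] = u1[2] * n[0] - u1[0] * n[2];
  u2[2] = u1[0] * n[1] - u1[1] * n[0];
  if (u2[0] * yax[0] + u2[1] * yax[1] + u2[2] * yax[2] < 0) {
    u2[0] = -u2[0]; u2[1] = -u2[1]; u2[2] = -u2[2];
  }
}

static inline int sector_code_point(double px, double py, double pz,
                                    const double *cor, const double *n,
                                    const double *u1, const double *u2,
                                    double roi_radius, double medial_offset,
                                    const double *centers,
                                    const double *halfw) {
  const double dx = px - cor[0], dy = py - cor[1], dz = pz - cor[2];
  if (dx * dx + dy * dy + dz * dz > roi_radius * roi_radius) return 0;
  const double an = dx * n[0] + dy * n[1] + dz * n[2];
  if (an < -medial_offset) return 4;  // Medial
  const double a1 = dx * u1[0] + dy * u1[1] + dz * u1[2];
  const double a2 = dx * u2[0] + dy * u2[1] + dz * u2[2];
  const double phi = std::atan2(a2, a1) * 180.0 / M_PI;
  int best = -1;
  double bestd = 1e30;
  for (int w = 0; w < 3; ++w) {
    double d = std::fabs(phi - centers[w]);
    if (d > 180.0) d = 360.0 - d;
    if (d <= halfw[w]) return w + 1;
    if (d < bestd) { bestd = d; best = w; }
  }
  return best + 1;  // gap between wedges: nearest center
}

// Sector code per point: 0 outside ROI, 1 Cranial, 2 Anterior, 3 Posterior,
// 4 Medial.
// [[Rcpp::export]]
IntegerVector classify_points_cpp(NumericMatrix P, NumericVector cor,
                                  NumericVector yaxis, NumericVector zaxis,
                                  NumericVector acet_normal, double roi_radius,
                                  double medial_offset,
                                  NumericVector wedge_centers,
                                  NumericVector wedge_halfwidths) {
  double u1[3], u2[3];
  sector_basis(acet_normal.begin(), zaxis.begin(), yaxis.begin(), u1, u2);
  const int np = P.nrow();
  IntegerVector out(np);
  for (int i = 0; i < np; ++i)
    out[i] = sector_code_point(P(i, 0), P(i, 1), P(i, 2), cor.begin(),
                               acet_normal.begin(), u1, u2, roi_radius,
                               medial_offset, wedge_centers.begin(),
                               wedge_halfwidths.begin());
  return out;
}

// Sector code per voxel center of a grid.
// [[Rcpp::export]]
IntegerVector classify_voxels_cpp(IntegerVector dims, NumericVector origin,
                                  double pitch, NumericVector cor,
                                  NumericVector yaxis, NumericVector zaxis,
                                  NumericVector acet_normal, double roi_radius,
                                  double medial_offset,
                                  NumericVector wedge_centers,
                                  NumericVector wedge_halfwidths) {
  double u1[3], u2[3];
  sector_basis(acet_normal.begin(), zaxis.begin(), yaxis.begin(), u1, u2);
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector out((size_t)nx * ny * nz);
  size_t s = 0;
  for (int k = 0; k < nz; ++k) {
    const double pz = origin[2] + (k + 0.5) * pitch;
    for (int j = 0; j < ny; ++j) {
      const double py = origin[1] + (j + 0.5) * pitch;
      for (int i = 0; i < nx; ++i, ++s) {
        const double px = origin[0] + (i + 0.5) * pitch;
        out[s] = sector_code_point(px, py, pz, cor.begin(),
                                   acet_normal.begin(), u1, u2, roi_radius,
                                   medial_offset, wedge_centers.begin(),
                                   wedge_halfwidths.begin());
      }
    }
  }
  return out;
}

// Occupied-voxel counts per sector code (returns length-5 vector for codes
// 0..4).
// [[Rcpp::export]]
NumericVector tally_codes_cpp(RawVector occ, IntegerVector codes) {
  NumericVector out(5);
  const R_xlen_t n = occ.size();
  for (R_xlen_t i = 0; i < n; ++i)
    if (occ[i] != 0) out[codes[i]] += 1.0;
  return out;
}

// Mask of voxels within `halfwidth` of a circle (center, unit normal,
// radius) -- the rim band.
// [[Rcpp::export]]
RawVector rim_band_mask_cpp(IntegerVector dims, NumericVector origin,
                            double pitch, NumericVector center,
                            NumericVector normal, double radius,
                            double halfwidth) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  RawVector out((size_t)nx * ny * nz);
  const double h2 = halfwidth * halfwidth;
  size_t s = 0;
  for (int k = 0; k < nz; ++k) {
    const double pz = origin[2] + (k + 0.5) * pitch;
    for (int j = 0; j < ny; ++j) {
      const double py = origin[1] + (j + 0.5) * pitch;
      for (int i = 0; i < nx; ++i, ++s) {
        const double px = origin[0] + (i + 0.5) * pitch;
        const double dx = px - center[0], dy = py - center[1],
                     dz = pz - center[2];
        const double ax = dx * normal[0] + dy * normal[1] + dz * normal[2];
        const double r2 = dx * dx + dy * dy + dz * dz - ax * ax;
        const double rad = std::sqrt(r2 > 0 ? r2 : 0) - radius;
        if (ax * ax + rad * rad <= h2) out[s] = 1;
      }
    }
  }
  return out;
}

static inline double dist2_point_tri(const double *p, const double *a,
                                     const double *b, const double *c) {
  // Ericson, Real-Time Collision Detection, closest point on triangle
  double ab[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  double ac[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
  double ap[3] = {p[0] - a[0], p[1] - a[1], p[2] - a[2]};
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  double q[3];
  if (d1 <= 0 && d2 <= 0) {
    q[0] = a[0]; q[1] = a[1]; q[2] = a[2];
  } else {
    double bp[3] = {p[0] - b[0], p[1] - b[1], p[2] - b[2]};
    double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
    double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
    if (d3 >= 0 && d4 <= d3) {
      q[0] = b[0]; q[1] = b[1]; q[2] = b[2];
    } else {
      double vc = d1 * d4 - d3 * d2;
      if (vc <= 0 && d1 >= 0 && d3 <= 0) {
        double v = d1 / (d1 - d3);
        for (int t = 0; t < 3; ++t) q[t] = a[t] + v * ab[t];
      } else {
        double cp[3] = {p[0] - c[0], p[1] - c[1], p[2] - c[2]};
        double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
        double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
        if (d6 >= 0 && d5 <= d6) {
          q[0] = c[0]; q[1] = c[1]; q[2] = c[2];
        } else {
          double vb = d5 * d2 - d1 * d6;
          if (vb <= 0 && d2 >= 0 && d6 <= 0) {
            double w = d2 / (d2 - d6);
            for (int t = 0; t < 3; ++t) q[t] = a[t] + w * ac[t];
          } else {
            double va = d3 * d6 - d5 * d4;
            if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
              double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
              for (int t = 0; t < 3; ++t) q[t] = b[t] + w * (c[t] - b[t]);
            } else {
              double denom = 1.0 / (va + vb + vc);
              double v = vb * denom, w = vc * denom;
              for (int t = 0; t < 3; ++t) q[t] = a[t] + ab[t] * v + ac[t] * w;
            }
          }
        }
      }
    }
  }
  double dx = p[0] - q[0], dy = p[1] - q[1], dz = p[2] - q[2];
  return dx * dx + dy * dy + dz * dz;
}

// Unsigned distance from each point to the surface of a triangle mesh.
// [[Rcpp::export]]
NumericVector dist_points_to_mesh_cpp(NumericMatrix P, NumericMatrix V,
                                      IntegerMatrix F) {
  const int np = P.nrow(), nf = F.nrow();
  NumericVector out(np);
  for (int i = 0; i < np; ++i) {
    const double p[3] = {P(i, 0), P(i, 1), P(i, 2)};
    double best = 1e30;
    for (int t = 0; t < nf; ++t) {
      const int ia = F(t, 0), ib = F(t, 1), ic = F(t, 2);
      const double a[3] = {V(ia, 0), V(ia, 1), V(ia, 2)};
      const double b[3] = {V(ib, 0), V(ib, 1), V(ib, 2)};
      const double c[3] = {V(ic, 0), V(ic, 1), V(ic, 2)};
      // quick reject on vertex a
      const double rx = p[0] - a[0], ry = p[1] - a[1], rz = p[2] - a[2];
      const double ra = rx * rx + ry * ry + rz * rz;
      // edge lengths bound the triangle's extent around a
      if (ra > best) {
        const double e1 = (b[0] - a[0]) * (b[0] - a[0]) +
                          (b[1] - a[1]) * (b[1] - a[1]) +
                          (b[2] - a[2]) * (b[2] - a[2]);
        const double e2 = (c[0] - a[0]) * (c[0] - a[0]) +
                          (c[1] - a[1]) * (c[1] - a[1]) +
                          (c[2] - a[2]) * (c[2] - a[2]);
        const double ext = std::sqrt(std::max(e1, e2));
        const double lo = std::sqrt(ra) - ext;
        if (lo > 0 && lo * lo > best) continue;
      }
      const double d2 = dist2_point_tri(p, a, b, c);
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// ---- parametric hemipelvis phantom ----------------------------------------
// Constructive solid geometry of the phantom: a spherical bone shell around a
// hemispherical acetabular cavity with a cylindrical lateral opening; carved
// sphere bites, capsule punches and rim erosion arcs; added formation blobs.
// Signed distance conventions: negative inside bone.

struct PhantomGeom {
  double oc[3];      // outer ball center
  double R;          // outer ball radius
  double rac;        // acetabular (cavity) radius
  NumericMatrix bites;     // cx, cy, cz, r
  NumericMatrix punches;   // ax, ay, az, bx, by, bz, r
  NumericMatrix erosions;  // phi1, phi2 (deg), depth, rim_radius
  NumericMatrix blobs;     // cx, cy, cz, r
  double imp[4];           // implant center + radius
};

static PhantomGeom parse_geom(List g) {
  PhantomGeom out;
  NumericVector oc = g["outer_center"];
  out.oc[0] = oc[0]; out.oc[1] = oc[1]; out.oc[2] = oc[2];
  out.R = as<double>(g["outer_radius"]);
  out.rac = as<double>(g["acetabular_radius"]);
  out.bites = as<NumericMatrix>(g["bites"]);
  out.punches = as<NumericMatrix>(g["punches"]);
  out.erosions = as<NumericMatrix>(g["erosions"]);
  out.blobs = as<NumericMatrix>(g["blobs"]);
  NumericVector imp = g["implant"];
  for (int i = 0; i < 4; ++i) out.imp[i] = imp.size() == 4 ? imp[i] : 0.0;
  return out;
}

static inline double sd_sphere(double x, double y, double z, const double *c,
                               double r) {
  const double dx = x - c[0], dy = y - c[1], dz = z - c[2];
  return std::sqrt(dx * dx + dy * dy + dz * dz) - r;
}

static inline double sd_capsule(double x, double y, double z,
                                const double *a, const double *b, double r) {
  const double abx = b[0] - a[0], aby = b[1] - a[1], abz = b[2] - a[2];
  const double apx = x - a[0], apy = y - a[1], apz = z - a[2];
  double h = (apx * abx + apy * aby + apz * abz) /
             (abx * abx + aby * aby + abz * abz);
  if (h < 0) h = 0;
  if (h > 1) h = 1;
  const double dx = apx - h * abx, dy = apy - h * aby, dz = apz - h * abz;
  return std::sqrt(dx * dx + dy * dy + dz * dz) - r;
}

// distance to an arc of the rim circle (plane x = 0, center origin,
// radius rr), azimuth measured from +z toward +y, minus the tube depth
static inline double sd_arc(double x, double y, double z, double phi1,
                            double phi2, double depth, double rr) {
  double phi = std::atan2(y, z) * 180.0 / M_PI;
  const double mid = (phi1 + phi2) / 2.0, half = (phi2 - phi1) / 2.0;
  double d = phi - mid;
  while (d > 180.0) d -= 360.0;
  while (d < -180.0) d += 360.0;
  if (d > half) d = half;
  if (d < -half) d = -half;
  const double pn = (mid + d) * M_PI / 180.0;
  const double ay = rr * std::sin(pn), az = rr * std::cos(pn);
  const double dy = y - ay, dz = z - az;
  return std::sqrt(x * x + dy * dy + dz * dz) - depth;
}

static inline double sd_native(double x, double y, double z,
                               const PhantomGeom &g) {
  const double outer = sd_sphere(x, y, z, g.oc, g.R);
  const double zero[3] = {0, 0, 0};
  const double ball = sd_sphere(x, y, z, zero, g.rac);
  const double rho = std::sqrt(y * y + z * z);
  const double cyl = std::max(-x, rho - g.rac);
  const double cavity = std::min(ball, cyl);
  return std::max(outer, -cavity);
}

static inline double sd_defect(double x, double y, double z,
                               const PhantomGeom &g) {
  double f = sd_native(x, y, z, g);
  for (int i = 0; i < g.bites.nrow(); ++i) {
    const double c[3] = {g.bites(i, 0), g.bites(i, 1), g.bites(i, 2)};
    f = std::max(f, -sd_sphere(x, y, z, c, g.bites(i, 3)));
  }
  for (int i = 0; i < g.punches.nrow(); ++i) {
    const double a[3] = {g.punches(i, 0), g.punches(i, 1), g.punches(i, 2)};
    const double b[3] = {g.punches(i, 3), g.punches(i, 4), g.punches(i, 5)};
    f = std::max(f, -sd_capsule(x, y, z, a, b, g.punches(i, 6)));
  }
  for (int i = 0; i < g.erosions.nrow(); ++i)
    f = std::max(f, -sd_arc(x, y, z, g.erosions(i, 0), g.erosions(i, 1),
                            g.erosions(i, 2), g.erosions(i, 3)));
  for (int i = 0; i < g.blobs.nrow(); ++i) {
    const double c[3] = {g.blobs(i, 0), g.blobs(i, 1), g.blobs(i, 2)};
    f = std::min(f, sd_sphere(x, y, z, c, g.blobs(i, 3)));
  }
  return f;
}

static inline double sd_implant(double x, double y, double z,
                                const PhantomGeom &g) {
  // solid hemispherical cup: ball clipped by the plane through its center
  // with lateral (+x) normal; articulating surface is the spherical part
  const double c[3] = {g.imp[0], g.imp[1], g.imp[2]};
  return std::max(sd_sphere(x, y, z, c, g.imp[3]), x - g.imp[0]);
}

// Scalar field at grid nodes (for marching tetrahedra).
// [[Rcpp::export]]
NumericVector phantom_field_cpp(NumericVector origin, double pitch,
                                IntegerVector ndim, List geom,
                                std::string what) {
  const PhantomGeom g = parse_geom(geom);
  const int nnx = ndim[0], nny = ndim[1], nnz = ndim[2];
  NumericVector out((size_t)nnx * nny * nnz);
  size_t s = 0;
  for (int k = 0; k < nnz; ++k) {
    const double z = origin[2] + k * pitch;
    for (int j = 0; j < nny; ++j) {
      const double y = origin[1] + j * pitch;
      for (int i = 0; i < nnx; ++i, ++s) {
        const double x = origin[0] + i * pitch;
        if (what == "native")
          out[s] = sd_native(x, y, z, g);
        else if (what == "defect")
          out[s] = sd_defect(x, y, z, g);
        else
          out[s] = sd_implant(x, y, z, g);
      }
    }
  }
  return out;
}

// Signed distances at arbitrary points.
// [[Rcpp::export]]
NumericVector phantom_sdf_cpp(NumericMatrix P, List geom, std::string what) {
  const PhantomGeom g = parse_geom(geom);
  NumericVector out(P.nrow());
  for (int i = 0; i < P.nrow(); ++i) {
    if (what == "native")
      out[i] = sd_native(P(i, 0), P(i, 1), P(i, 2), g);
    else if (what == "defect")
      out[i] = sd_defect(P(i, 0), P(i, 1), P(i, 2), g);
    else
      out[i] = sd_implant(P(i, 0), P(i, 1), P(i, 2), g);
  }
  return out;
}

// Ground-truth tallies over the voxel centers of the axis-aligned box
// [lo, hi): per-sector-code (0..4) voxel counts of native bone, bone loss
// (native & !defect) and formation (defect & !native), each * pitch^3 in
// mm^3.
// [[Rcpp::export]]
List phantom_truth_cpp(NumericVector lo, NumericVector hi, double pitch,
                       List geom, List sector) {
  const PhantomGeom g = parse_geom(geom);
  NumericVector cor = sector["cor"], yax = sector["yaxis"],
                zax = sector["zaxis"], nrm = sector["normal"],
                centers = sector["wedge_centers"],
                halfw = sector["wedge_halfwidths"];
  const double roi = as<double>(sector["roi_radius"]);
  const double moff = as<double>(sector["medial_offset"]);
  double u1[3], u2[3];
  sector_basis(nrm.begin(), zax.begin(), yax.begin(), u1, u2);

  const int nx = (int)std::ceil((hi[0] - lo[0]) / pitch);
  const int ny = (int)std::ceil((hi[1] - lo[1]) / pitch);
  const int nz = (int)std::ceil((hi[2] - lo[2]) / pitch);
  NumericVector nat(5), loss(5), form(5);
  // membership with early exit: defect = (native minus carves) union blobs
  auto in_carve = [&](double x, double y, double z) -> bool {
    for (int i = 0; i < g.bites.nrow(); ++i) {
      const double c[3] = {g.bites(i, 0), g.bites(i, 1), g.bites(i, 2)};
      if (sd_sphere(x, y, z, c, g.bites(i, 3)) < 0) return true;
    }
    for (int i = 0; i < g.punches.nrow(); ++i) {
      const double a[3] = {g.punches(i, 0), g.punches(i, 1), g.punches(i, 2)};
      const double b[3] = {g.punches(i, 3), g.punches(i, 4), g.punches(i, 5)};
      if (sd_capsule(x, y, z, a, b, g.punches(i, 6)) < 0) return true;
    }
    for (int i = 0; i < g.erosions.nrow(); ++i)
      if (sd_arc(x, y, z, g.erosions(i, 0), g.erosions(i, 1),
                 g.erosions(i, 2), g.erosions(i, 3)) < 0)
        return true;
    return false;
  };
  auto in_blob = [&](double x, double y, double z) -> bool {
    for (int i = 0; i < g.blobs.nrow(); ++i) {
      const double c[3] = {g.blobs(i, 0), g.blobs(i, 1), g.blobs(i, 2)};
      if (sd_sphere(x, y, z, c, g.blobs(i, 3)) < 0) return true;
    }
    return false;
  };
  for (int k = 0; k < nz; ++k) {
    const double z = lo[2] + (k + 0.5) * pitch;
    for (int j = 0; j < ny; ++j) {
      const double y = lo[1] + (j + 0.5) * pitch;
      for (int i = 0; i < nx; ++i) {
        const double x = lo[0] + (i + 0.5) * pitch;
        const bool in_nat = sd_native(x, y, z, g) < 0;
        bool in_def;
        if (in_nat)
          in_def = !in_carve(x, y, z) || in_blob(x, y, z);
        else
          in_def = in_blob(x, y, z);
        if (!in_nat && !in_def) continue;
        const int code = sector_code_point(x, y, z, cor.begin(), nrm.begin(),
                                           u1, u2, roi, moff,
                                           centers.begin(), halfw.begin());
        if (in_nat) nat[code] += 1.0;
        if (in_nat && !in_def) loss[code] += 1.0;
        if (in_def && !in_nat) form[code] += 1.0;
      }
    }
  }
  const double v = pitch * pitch * pitch;
  for (int c = 0; c < 5; ++c) {
    nat[c] *= v; loss[c] *= v; form[c] *= v;
  }
  return List::create(_["native_mm3"] = nat, _["loss_mm3"] = loss,
                      _["formation_mm3"] = form);
}
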