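#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>
#include <queue>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Isosurface extraction: marching tetrahedra on a scalar grid.
//
// Each grid cell (8 voxel centers) is split into 6 tetrahedra sharing the
// main diagonal; each tetrahedron contributes 0, 1 or 2 triangles. Surface
// vertices are interpolated on lattice edges and de-duplicated by the pair
// of lattice node ids carrying them, so the mesh is vertex-shared and, for
// fields whose foreground does not touch the array border, closed. Triangle
// winding is fixed per-triangle so face normals point away from the
// above-iso (foreground) side.
// ---------------------------------------------------------------------------

struct MTState {
  std::unordered_map<uint64_t, int> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> fa, fb, fc;
};

static inline int edge_point(MTState &st, uint64_t na, uint64_t nb,
                             const double *pa, const double *pb,
                             double va, double vb, double iso) {
  uint64_t lo = na < nb ? na : nb, hi = na < nb ? nb : na;
  uint64_t key = lo * 0x100000000ULL ^ hi;
  auto it = st.edge_vertex.find(key);
  if (it != st.edge_vertex.end()) return it->second;
  // interpolate in a fixed node order so shared edges agree bit-for-bit
  const double *plo = na < nb ? pa : pb, *phi = na < nb ? pb : pa;
  double vlo = na < nb ? va : vb, vhi = na < nb ? vb : va;
  double t = (iso - vlo) / (vhi - vlo);
  if (t < 0.0) t = 0.0;
  if (t > 1.0) t = 1.0;
  int id = (int)st.vx.size();
  st.vx.push_back(plo[0] + t * (phi[0] - plo[0]));
  st.vy.push_back(plo[1] + t * (phi[1] - plo[1]));
  st.vz.push_back(plo[2] + t * (phi[2] - plo[2]));
  st.edge_vertex.emplace(key, id);
  return id;
}

static inline void emit_tri(MTState &st, int a, int b, int c,
                            const double *inside_centroid) {
  if (a == b || b == c || a == c) return;  // degenerate (iso hits a node)
  double ax = st.vx[a], ay = st.vy[a], az = st.vz[a];
  double ux = st.vx[b] - ax, uy = st.vy[b] - ay, uz = st.vz[b] - az;
  double wx = st.vx[c] - ax, wy = st.vy[c] - ay, wz = st.vz[c] - az;
  double nx = uy * wz - uz * wy, ny = uz * wx - ux * wz, nz = ux * wy - uy * wx;
  double cx = (ax + st.vx[b] + st.vx[c]) / 3.0 - inside_centroid[0];
  double cy = (ay + st.vy[b] + st.vy[c]) / 3.0 - inside_centroid[1];
  double cz = (az + st.vz[b] + st.vz[c]) / 3.0 - inside_centroid[2];
  if (nx * cx + ny * cy + nz * cz < 0.0) std::swap(b, c);
  st.fa.push_back(a + 1); st.fb.push_back(b + 1); st.fc.push_back(c + 1);
}

// [[Rcpp::export]]
List mt_isosurface(NumericVector field, NumericVector spacing,
                   NumericVector origin, double iso) {
  IntegerVector dim = field.attr("dim");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const double *f = field.begin();

  // cube corner offsets, corner 0 at (i,j,k), corner 6 at (i+1,j+1,k+1)
  static const int co[8][3] = {{0,0,0},{1,0,0},{1,1,0},{0,1,0},
                               {0,0,1},{1,0,1},{1,1,1},{0,1,1}};
  static const int tets[6][4] = {{0,5,1,6},{0,1,2,6},{0,2,3,6},
                                 {0,3,7,6},{0,7,4,6},{0,4,5,6}};
  MTState st;
  uint64_t nid[8];
  double pos[8][3], val[8];

  for (int k = 0; k < nz - 1; ++k)
    for (int j = 0; j < ny - 1; ++j)
      for (int i = 0; i < nx - 1; ++i) {
        bool any = false, all = true;
        for (int c = 0; c < 8; ++c) {
          int ii = i + co[c][0], jj = j + co[c][1], kk = k + co[c][2];
          uint64_t id = (uint64_t)ii + (uint64_t)nx * ((uint64_t)jj + (uint64_t)ny * kk);
          nid[c] = id;
          val[c] = f[id];
          pos[c][0] = ox + ii * sx; pos[c][1] = oy + jj * sy; pos[c][2] = oz + kk * sz;
          if (val[c] > iso) any = true; else all = false;
        }
        if (!any || all) continue;
        for (int t = 0; t < 6; ++t) {
          const int *tv = tets[t];
          int in[4], nin = 0, out[4], nout = 0;
          for (int c = 0; c < 4; ++c) {
            if (val[tv[c]] > iso) in[nin++] = tv[c]; else out[nout++] = tv[c];
          }
          if (nin == 0 || nin == 4) continue;
          double ic[3] = {0, 0, 0};
          for (int c = 0; c < nin; ++c)
            for (int d = 0; d < 3; ++d) ic[d] += pos[in[c]][d] / nin;
          if (nin == 1) {
            int A = in[0];
            int e0 = edge_point(st, nid[A], nid[out[0]], pos[A], pos[out[0]], val[A], val[out[0]], iso);
            int e1 = edge_point(st, nid[A], nid[out[1]], pos[A], pos[out[1]], val[A], val[out[1]], iso);
            int e2 = edge_point(st, nid[A], nid[out[2]], pos[A], pos[out[2]], val[A], val[out[2]], iso);
            emit_tri(st, e0, e1, e2, ic);
          } else if (nin == 3) {
            int D = out[0];
            int e0 = edge_point(st, nid[D], nid[in[0]], pos[D], pos[in[0]], val[D], val[in[0]], iso);
            int e1 = edge_point(st, nid[D], nid[in[1]], pos[D], pos[in[1]], val[D], val[in[1]], iso);
            int e2 = edge_point(st, nid[D], nid[in[2]], pos[D], pos[in[2]], val[D], val[in[2]], iso);
            emit_tri(st, e0, e1, e2, ic);
          } else {  // 2 in, 2 out: quad AC-AD-BD-BC split into two triangles
            int A = in[0], B = in[1], C = out[0], D = out[1];
            int eAC = edge_point(st, nid[A], nid[C], pos[A], pos[C], val[A], val[C], iso);
            int eAD = edge_point(st, nid[A], nid[D], pos[A], pos[D], val[A], val[D], iso);
            int eBD = edge_point(st, nid[B], nid[D], pos[B], pos[D], val[B], val[D], iso);
            int eBC = edge_point(st, nid[B], nid[C], pos[B], pos[C], val[B], val[C], iso);
            emit_tri(st, eAC, eAD, eBD, ic);
            emit_tri(st, eAC, eBD, eBC, ic);
          }
        }
      }

  int nv = (int)st.vx.size(), nf = (int)st.fa.size();
  NumericMatrix V(nv, 3);
  for (int v = 0; v < nv; ++v) { V(v,0) = st.vx[v]; V(v,1) = st.vy[v]; V(v,2) = st.vz[v]; }
  IntegerMatrix F(nf, 3);
  for (int t = 0; t < nf; ++t) { F(t,0) = st.fa[t]; F(t,1) = st.fb[t]; F(t,2) = st.fc[t]; }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform (squared-parabola lower envelope),
// separable over axes with anisotropic spacing. Distance is measured FROM
// the foreground mask, in world mm (0 inside the mask).
// ---------------------------------------------------------------------------

static void dt1d(std::vector<double> &frow, int n, double s,
                 std::vector<double> &d, std::vector<int> &v, std::vector<double> &z) {
  const double s2 = s * s;
  int kk = 0;
  v[0] = 0;
  z[0] = -INFINITY; z[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double sden, snum;
    while (true) {
      snum = (frow[q] + s2 * q * q) - (frow[v[kk]] + s2 * (double)v[kk] * v[kk]);
      sden = 2.0 * s2 * (q - v[kk]);
      double cross = snum / sden;
      if (cross <= z[kk]) { --kk; } else { ++kk; v[kk] = q; z[kk] = cross; z[kk+1] = INFINITY; break; }
    }
  }
  kk = 0;
  for (int q = 0; q < n; ++q) {
    while (z[kk + 1] < q) ++kk;
    double dq = (double)q - v[kk];
    d[q] = s2 * dq * dq + frow[v[kk]];
  }
  for (int q = 0; q < n; ++q) frow[q] = d[q];
}

// [[Rcpp::export]]
NumericVector edt3d(LogicalVector mask, NumericVector spacing) {
  IntegerVector dim = mask.attr("dim");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double BIG = 1e20;  // finite sentinel keeps envelope arithmetic valid
  NumericVector D(n);
  for (R_xlen_t t = 0; t < n; ++t) D[t] = mask[t] ? 0.0 : BIG;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> row(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      bool anyf = false;
      for (int i = 0; i < nx; ++i) { row[i] = D[base + i]; if (row[i] < BIG) anyf = true; }
      if (!anyf) continue;
      dt1d(row, nx, spacing[0], d, v, z);
      for (int i = 0; i < nx; ++i) D[base + i] = row[i];
    }
  // y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + (R_xlen_t)nx * ny * (R_xlen_t)k;
      bool anyf = false;
      for (int j = 0; j < ny; ++j) { row[j] = D[base + (R_xlen_t)nx * j]; if (row[j] < BIG) anyf = true; }
      if (!anyf) continue;
      dt1d(row, ny, spacing[1], d, v, z);
      for (int j = 0; j < ny; ++j) D[base + (R_xlen_t)nx * j] = row[j];
    }
  // z
  const R_xlen_t stz = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + (R_xlen_t)nx * j;
      bool anyf = false;
      for (int k = 0; k < nz; ++k) { row[k] = D[base + stz * k]; if (row[k] < BIG) anyf = true; }
      if (!anyf) continue;
      dt1d(row, nz, spacing[2], d, v, z);
      for (int k = 0; k < nz; ++k) D[base + stz * k] = row[k];
    }
  for (R_xlen_t t = 0; t < n; ++t) D[t] = (D[t] >= BIG) ? R_PosInf : std::sqrt(D[t]);
  D.attr("dim") = dim;
  return D;
}

// ---------------------------------------------------------------------------
// Nearest mesh vertex for each query point, via a uniform hash grid.
// Ties (equal distance within 1e-9 mm^2) resolve to the lowest vertex id,
// so assignments are reproducible across runs and platforms.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector nearest_vertex_ids(NumericMatrix verts, NumericMatrix pts, double cell) {
  const int nv = verts.nrow(), np = pts.nrow();
  IntegerVector out(np);
  if (nv == 0) stop("mesh has no vertices");
  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) { lo[d] = verts(0,d); hi[d] = verts(0,d); }
  for (int v = 1; v < nv; ++v)
    for (int d = 0; d < 3; ++d) {
      if (verts(v,d) < lo[d]) lo[d] = verts(v,d);
      if (verts(v,d) > hi[d]) hi[d] = verts(v,d);
    }
  int gdim[3];
  for (int d = 0; d < 3; ++d)
    gdim[d] = std::max(1, (int)std::floor((hi[d] - lo[d]) / cell) + 1);
  auto cell_of = [&](double x, int d) {
    int c = (int)std::floor((x - lo[d]) / cell);
    if (c < 0) c = 0;
    if (c >= gdim[d]) c = gdim[d] - 1;
    return c;
  };
  std::vector<std::vector<int>> bins((size_t)gdim[0] * gdim[1] * gdim[2]);
  for (int v = 0; v < nv; ++v) {
    size_t b = cell_of(verts(v,0),0) + (size_t)gdim[0] *
               (cell_of(verts(v,1),1) + (size_t)gdim[1] * cell_of(verts(v,2),2));
    bins[b].push_back(v);
  }
  int rmax = std::max(gdim[0], std::max(gdim[1], gdim[2]));
  for (int p = 0; p < np; ++p) {
    double qx = pts(p,0), qy = pts(p,1), qz = pts(p,2);
    int ci = cell_of(qx,0), cj = cell_of(qy,1), ck = cell_of(qz,2);
    double best = INFINITY;
    int bestid = -1;
    for (int r = 0; r <= rmax; ++r) {
      // once a hit exists, stop when the ring cannot beat it
      if (bestid >= 0) {
        double ringmin = (r - 1) * cell;  // conservative lower bound
        if (ringmin > 0 && ringmin * ringmin > best) break;
      }
      bool ring_in_grid = false;
      for (int dk = -r; dk <= r; ++dk) {
        int k = ck + dk;
        if (k < 0 || k >= gdim[2]) continue;
        for (int dj = -r; dj <= r; ++dj) {
          int j = cj + dj;
          if (j < 0 || j >= gdim[1]) continue;
          for (int di = -r; di <= r; ++di) {
            if (std::max(std::abs(di), std::max(std::abs(dj), std::abs(dk))) != r) continue;
            int i = ci + di;
            if (i < 0 || i >= gdim[0]) continue;
            ring_in_grid = true;
            const std::vector<int> &b = bins[i + (size_t)gdim[0] * (j + (size_t)gdim[1] * k)];
            for (int v : b) {
              double dx = verts(v,0) - qx, dy = verts(v,1) - qy, dz = verts(v,2) - qz;
              double d2 = dx*dx + dy*dy + dz*dz;
              if (d2 < best - 1e-9 || (std::fabs(d2 - best) <= 1e-9 && v < bestid)) {
                best = d2; bestid = v;
              }
            }
          }
        }
      }
      if (!ring_in_grid && bestid >= 0) break;
      if (!ring_in_grid && r > rmax) break;
    }
    out[p] = bestid + 1;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Normal-ray EAT adjacency. For each wall voxel, sample the outward ray at
// t = step, 2*step, ..., <= depth; nearest-voxel lookup per sample. Samples
// inside the wall are skipped (intramural voxel centers may sit mid-wall);
// samples off the grid terminate the ray; the flag is set on the first
// sample landing in the EAT mask.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
LogicalVector ray_adjacency(NumericMatrix centers, NumericMatrix normals,
                            LogicalVector eat, LogicalVector wall,
                            IntegerVector dim, NumericVector spacing,
                            NumericVector origin, double depth, double step) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int np = centers.nrow();
  const int nsteps = (int)std::floor(depth / step + 1e-9);
  LogicalVector out(np);
  for (int p = 0; p < np; ++p) {
    bool hit = false;
    for (int m = 1; m <= nsteps && !hit; ++m) {
      double t = m * step;
      double x = centers(p,0) + t * normals(p,0);
      double y = centers(p,1) + t * normals(p,1);
      double z = centers(p,2) + t * normals(p,2);
      int i = (int)std::llround((x - origin[0]) / spacing[0]);
      int j = (int)std::llround((y - origin[1]) / spacing[1]);
      int k = (int)std::llround((z - origin[2]) / spacing[2]);
      if (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz) break;
      R_xlen_t id = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      if (wall[id]) continue;
      if (eat[id]) hit = true;
    }
    out[p] = hit;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Mask topology helpers: 26-connected component labelling, and 6-connected
// reachability of background from the array border (for shell enclosure).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector label_components26(LogicalVector mask) {
  IntegerVector dim = mask.attr("dim");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    stack.push_back(s);
    lab[s] = next;
    while (!stack.empty()) {
      R_xlen_t cur = stack.back(); stack.pop_back();
      int i = (int)(cur % nx), j = (int)((cur / nx) % ny), k = (int)(cur / ((R_xlen_t)nx * ny));
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
            R_xlen_t q = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
            if (mask[q] && !lab[q]) { lab[q] = next; stack.push_back(q); }
          }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// [[Rcpp::export]]
LogicalVector reachable_from_border(LogicalVector barrier) {
  IntegerVector dim = barrier.attr("dim");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector seen(n, false);
  std::vector<R_xlen_t> stack;
  auto push = [&](int i, int j, int k) {
    R_xlen_t q = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
    if (!barrier[q] && !seen[q]) { seen[q] = true; stack.push_back(q); }
  };
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i)
        if (i == 0 || j == 0 || k == 0 || i == nx-1 || j == ny-1 || k == nz-1) push(i, j, k);
  static const int off[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  while (!stack.empty()) {
    R_xlen_t cur = stack.back(); stack.pop_back();
    int i = (int)(cur % nx), j = (int)((cur / nx) % ny), k = (int)(cur / ((R_xlen_t)nx * ny));
    for (const int *o : off) {
      int ii = i + o[0], jj = j + o[1], kk = k + o[2];
      if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
      push(ii, jj, kk);
    }
  }
  seen.attr("dim") = dim;
  return seen;
}

// Separable Gaussian smoothing with per-axis sigma in voxels (reflected
// borders). Used to regularise binary masks before isosurface extraction.
// [[Rcpp::export]]
NumericVector gaussian_smooth3d(NumericVector vol, NumericVector sigma_vox) {
  IntegerVector dim = vol.attr("dim");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector cur = clone(vol);
  const int nd[3] = {nx, ny, nz};
  const R_xlen_t stride[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma_vox[ax];
    if (s <= 0) continue;
    int half = std::max(1, (int)std::ceil(3.0 * s));
    std::vector<double> kern(2 * half + 1);
    double ksum = 0;
    for (int t = -half; t <= half; ++t) { kern[t + half] = std::exp(-0.5 * t * t / (s * s)); ksum += kern[t + half]; }
    for (double &w : kern) w /= ksum;
    NumericVector nxt(cur.size());
    int n = nd[ax];
    R_xlen_t st = stride[ax];
    // iterate over all lines along axis ax
    int o1 = (ax == 0) ? 1 : 0, o2 = (ax == 2) ? 1 : 2;
    for (int b = 0; b < nd[o2]; ++b)
      for (int a = 0; a < nd[o1]; ++a) {
        R_xlen_t base = (R_xlen_t)a * stride[o1] + (R_xlen_t)b * stride[o2];
        for (int q = 0; q < n; ++q) {
          double acc = 0;
          for (int t = -half; t <= half; ++t) {
            int u = q + t;
            if (u < 0) u = -u - 1;
            if (u >= n) u = 2 * n - u - 1;
            acc += kern[t + half] * cur[base + st * u];
          }
          nxt[base + st * q] = acc;
        }
      }
    nxt.attr("dim") = dim;
    cur = nxt;
  }
  cur.attr("dim") = dim;
  return cur;
}
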