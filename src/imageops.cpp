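#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Arrays are stored column-major with dim = c(nz, ny, nx): axis order (z, y, x).
// Linear index: z + nz * (y + ny * x).

static inline int lin(int z, int y, int x, int nz, int ny) {
  return z + nz * (y + ny * x);
}

// 26-connected (or 6-connected) component labeling by flood fill.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dims, int connectivity) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  IntegerVector labels(mask.size(), 0);
  std::vector<int> stack;
  int next = 0;
  for (int x0 = 0; x0 < nx; ++x0) for (int y0 = 0; y0 < ny; ++y0)
    for (int z0 = 0; z0 < nz; ++z0) {
      int i0 = lin(z0, y0, x0, nz, ny);
      if (!mask[i0] || labels[i0]) continue;
      ++next;
      labels[i0] = next;
      stack.push_back(i0);
      while (!stack.empty()) {
        int i = stack.back(); stack.pop_back();
        int x = i / (nz * ny), rem = i % (nz * ny), y = rem / nz, z = rem % nz;
        for (int dx = -1; dx <= 1; ++dx) for (int dy = -1; dy <= 1; ++dy)
          for (int dz = -1; dz <= 1; ++dz) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            if (connectivity == 6 && std::abs(dx) + std::abs(dy) + std::abs(dz) > 1)
              continue;
            int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
              continue;
            int j = lin(zz, yy, xx, nz, ny);
            if (mask[j] && !labels[j]) { labels[j] = next; stack.push_back(j); }
          }
      }
    }
  labels.attr("dim") = dims;
  return labels;
}

// 1D squared distance transform (Felzenszwalb & Huttenlocher) with grid spacing h.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, double h) {
  int n = (int)f.size();
  const double INF = std::numeric_limits<double>::infinity();
  int q0 = 0;
  while (q0 < n && f[q0] == INF) ++q0;
  if (q0 == n) { for (int q = 0; q < n; ++q) d[q] = INF; return; }
  std::vector<int> v(n);
  std::vector<double> zb(n + 1);
  int k = 0;
  v[0] = q0; zb[0] = -INF; zb[1] = INF;
  auto intersect = [&](int q, int p) {
    double xq = q * h, xp = p * h;
    return ((f[q] + xq * xq) - (f[p] + xp * xp)) / (2 * xq - 2 * xp);
  };
  for (int q = q0 + 1; q < n; ++q) {
    if (f[q] == INF) continue;
    double s = intersect(q, v[k]);
    while (s <= zb[k]) { --k; s = intersect(q, v[k]); }
    ++k; v[k] = q; zb[k] = s; zb[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * h;
    while (zb[k + 1] < xq) ++k;
    double df = xq - v[k] * h;
    d[q] = df * df + f[v[k]];
  }
}

// Exact anisotropic Euclidean distance transform: distance (in physical units)
// of each foreground voxel to the nearest background voxel. Background gets 0.
// spacing is c(z, y, x).
// [[Rcpp::export]]
NumericVector cpp_edt3d(LogicalVector mask, IntegerVector dims, NumericVector spacing) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> g(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) g[i] = mask[i] ? INF : 0.0;
  // Outside the grid is not treated as background: the transform measures
  // distance to the image background, and phantoms always carry a margin.
  std::vector<double> f, d;
  // pass along z
  f.resize(nz); d.resize(nz);
  for (int x = 0; x < nx; ++x) for (int y = 0; y < ny; ++y) {
    for (int z = 0; z < nz; ++z) f[z] = g[lin(z, y, x, nz, ny)];
    dt1d(f, d, spacing[0]);
    for (int z = 0; z < nz; ++z) g[lin(z, y, x, nz, ny)] = d[z];
  }
  // pass along y
  f.resize(ny); d.resize(ny);
  for (int x = 0; x < nx; ++x) for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) f[y] = g[lin(z, y, x, nz, ny)];
    dt1d(f, d, spacing[1]);
    for (int y = 0; y < ny; ++y) g[lin(z, y, x, nz, ny)] = d[y];
  }
  // pass along x
  f.resize(nx); d.resize(nx);
  for (int y = 0; y < ny; ++y) for (int z = 0; z < nz; ++z) {
    for (int x = 0; x < nx; ++x) f[x] = g[lin(z, y, x, nz, ny)];
    dt1d(f, d, spacing[2]);
    for (int x = 0; x < nx; ++x) g[lin(z, y, x, nz, ny)] = d[x];
  }
  NumericVector out(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) out[i] = std::sqrt(g[i]);
  out.attr("dim") = dims;
  return out;
}

// Binary erosion with the 6-connected cross structuring element.
// with_z[it] says whether iteration it erodes along z as well (anisotropic
// voxels: the caller schedules z erosions so the removed depth stays
// approximately isotropic in physical units).
// [[Rcpp::export]]
LogicalVector cpp_erode6(LogicalVector mask, IntegerVector dims, int n_iter,
                         LogicalVector with_z) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  std::vector<char> cur(mask.size()), nxt(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) cur[i] = mask[i] ? 1 : 0;
  const int off[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  for (int it = 0; it < n_iter; ++it) {
    bool do_z = it < with_z.size() ? (bool)with_z[it] : true;
    int k0 = do_z ? 0 : 2;
    for (int x = 0; x < nx; ++x) for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        int i = lin(z, y, x, nz, ny);
        char keep = cur[i];
        if (keep) {
          for (int k = k0; k < 6 && keep; ++k) {
            int zz = z + off[k][0], yy = y + off[k][1], xx = x + off[k][2];
            if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
              { keep = 0; break; }
            if (!cur[lin(zz, yy, xx, nz, ny)]) keep = 0;
          }
        }
        nxt[i] = keep;
      }
    std::swap(cur, nxt);
  }
  LogicalVector out(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) out[i] = cur[i] != 0;
  out.attr("dim") = dims;
  return out;
}

// Expand seed labels within a mask by multi-source BFS (6-connected) without
// label merging: every mask voxel reachable from a seed gets the label of the
// nearest (in BFS order) seed.
// [[Rcpp::export]]
IntegerVector cpp_expand_labels(IntegerVector seeds, LogicalVector mask, IntegerVector dims) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  IntegerVector out(seeds.size(), 0);
  std::queue<int> q;
  for (R_xlen_t i = 0; i < seeds.size(); ++i)
    if (seeds[i] > 0) { out[i] = seeds[i]; q.push((int)i); }
  const int off[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  while (!q.empty()) {
    int i = q.front(); q.pop();
    int x = i / (nz * ny), rem = i % (nz * ny), y = rem / nz, z = rem % nz;
    for (int k = 0; k < 6; ++k) {
      int zz = z + off[k][0], yy = y + off[k][1], xx = x + off[k][2];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
      int j = lin(zz, yy, xx, nz, ny);
      if (mask[j] && out[j] == 0) { out[j] = out[i]; q.push(j); }
    }
  }
  out.attr("dim") = dims;
  return out;
}

// Isosurface area by marching tetrahedra on the Kuhn 6-tetrahedron cube
// decomposition. vol holds scalar values at voxel centers; spacing c(z,y,x).
// [[Rcpp::export]]
double cpp_march_area(NumericVector vol, IntegerVector dims, NumericVector spacing, double iso) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  double sz = spacing[0], sy = spacing[1], sx = spacing[2];
  // corners of unit cube indexed by bits (bx, by, bz)
  static const int corner[8][3] = {
    {0,0,0},{1,0,0},{0,1,0},{1,1,0},{0,0,1},{1,0,1},{0,1,1},{1,1,1}};
  // 6 monotone bit-flip paths 000 -> 111 (Kuhn triangulation), corner ids
  static const int tets[6][4] = {
    {0,1,3,7},{0,1,5,7},{0,2,3,7},{0,2,6,7},{0,4,5,7},{0,4,6,7}};
  double area = 0.0;
  double P[8][3], F[8];
  for (int x = 0; x < nx - 1; ++x) for (int y = 0; y < ny - 1; ++y)
    for (int z = 0; z < nz - 1; ++z) {
      bool anyAbove = false, anyBelow = false;
      for (int c = 0; c < 8; ++c) {
        int cx = x + corner[c][0], cy = y + corner[c][1], cz = z + corner[c][2];
        F[c] = vol[lin(cz, cy, cx, nz, ny)];
        P[c][0] = cx * sx; P[c][1] = cy * sy; P[c][2] = cz * sz;
        if (F[c] > iso) anyAbove = true; else anyBelow = true;
      }
      if (!anyAbove || !anyBelow) continue;
      for (int t = 0; t < 6; ++t) {
        int vi[4] = {tets[t][0], tets[t][1], tets[t][2], tets[t][3]};
        int above[4], below[4]; int na = 0, nb = 0;
        for (int k = 0; k < 4; ++k) {
          if (F[vi[k]] > iso) above[na++] = vi[k]; else below[nb++] = vi[k];
        }
        if (na == 0 || na == 4) continue;
        auto interp = [&](int a, int b, double* out) {
          double tt = (iso - F[a]) / (F[b] - F[a]);
          for (int d = 0; d < 3; ++d) out[d] = P[a][d] + tt * (P[b][d] - P[a][d]);
        };
        auto triArea = [](double* a, double* b, double* c) {
          double u[3], v[3];
          for (int d = 0; d < 3; ++d) { u[d] = b[d] - a[d]; v[d] = c[d] - a[d]; }
          double cx = u[1]*v[2]-u[2]*v[1], cy = u[2]*v[0]-u[0]*v[2], cz = u[0]*v[1]-u[1]*v[0];
          return 0.5 * std::sqrt(cx*cx + cy*cy + cz*cz);
        };
        if (na == 1 || na == 3) {
          int apex = (na == 1) ? above[0] : below[0];
          int* base = (na == 1) ? below : above;
          double p1[3], p2[3], p3[3];
          interp(apex, base[0], p1); interp(apex, base[1], p2); interp(apex, base[2], p3);
          area += triArea(p1, p2, p3);
        } else { // 2-2: quad on the four crossing edges
          double q1[3], q2[3], q3[3], q4[3];
          interp(above[0], below[0], q1); interp(above[0], below[1], q2);
          interp(above[1], below[1], q3); interp(above[1], below[0], q4);
          area += triArea(q1, q2, q3) + triArea(q1, q3, q4);
        }
      }
    }
  return area;
}

// Exposed voxel faces area for anisotropic voxels (literal voxel-counting estimator).
// [[Rcpp::export]]
double cpp_voxel_face_area(LogicalVector mask, IntegerVector dims, NumericVector spacing) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  double sz = spacing[0], sy = spacing[1], sx = spacing[2];
  double az = sx * sy;  // face perpendicular to z
  double ay = sx * sz;
  double ax = sy * sz;
  double area = 0.0;
  for (int x = 0; x < nx; ++x) for (int y = 0; y < ny; ++y)
    for (int z = 0; z < nz; ++z) {
      if (!mask[lin(z, y, x, nz, ny)]) continue;
      if (z == 0 || !mask[lin(z-1, y, x, nz, ny)]) area += az;
      if (z == nz-1 || !mask[lin(z+1, y, x, nz, ny)]) area += az;
      if (y == 0 || !mask[lin(z, y-1, x, nz, ny)]) area += ay;
      if (y == ny-1 || !mask[lin(z, y+1, x, nz, ny)]) area += ay;
      if (x == 0 || !mask[lin(z, y, x-1, nz, ny)]) area += ax;
      if (x == nx-1 || !mask[lin(z, y, x+1, nz, ny)]) area += ax;
    }
  return area;
}

// Minimum Euclidean distance from each query point to a point set (rows).
// [[Rcpp::export]]
NumericVector cpp_min_dist(NumericMatrix query, NumericMatrix set) {
  int nq = query.nrow(), ns = set.nrow(), d = query.ncol();
  NumericVector out(nq);
  for (int i = 0; i < nq; ++i) {
    double best = std::numeric_limits<double>::infinity();
    for (int j = 0; j < ns; ++j) {
      double s = 0;
      for (int k = 0; k < d; ++k) { double df = query(i, k) - set(j, k); s += df * df; }
      if (s < best) best = s;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
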