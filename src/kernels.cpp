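#include <Rcpp.h>
#include <algorithm>
#include <climits>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Trilinear sampling of a 3-D scalar grid at arbitrary physical points.
// vol is an R array with dims dim; voxel (i,j,k) (0-based) sits at
// origin + (i,j,k)*spacing. Points outside the grid get `fill` and inside=false.
// [[Rcpp::export(name = ".trilinear_sample_cpp")]]
List trilinear_sample_cpp(NumericVector vol, IntegerVector dim,
                          NumericVector spacing, NumericVector origin,
                          NumericMatrix pts, double fill) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = pts.nrow();
  NumericVector out(n);
  LogicalVector inside(n);
  const double *v = vol.begin();
  for (int p = 0; p < n; ++p) {
    double fx = (pts(p, 0) - origin[0]) / spacing[0];
    double fy = (pts(p, 1) - origin[1]) / spacing[1];
    double fz = (pts(p, 2) - origin[2]) / spacing[2];
    if (fx < 0 || fy < 0 || fz < 0 || fx > nx - 1 || fy > ny - 1 || fz > nz - 1) {
      out[p] = fill;
      inside[p] = false;
      continue;
    }
    int i0 = (int)std::floor(fx), j0 = (int)std::floor(fy), k0 = (int)std::floor(fz);
    if (i0 == nx - 1) i0--;
    if (j0 == ny - 1) j0--;
    if (k0 == nz - 1) k0--;
    double tx = fx - i0, ty = fy - j0, tz = fz - k0;
    const long sx = 1, sy = nx, sz = (long)nx * ny;
    const double *b = v + i0 * sx + j0 * sy + k0 * sz;
    double c00 = b[0] * (1 - tx) + b[sx] * tx;
    double c10 = b[sy] * (1 - tx) + b[sy + sx] * tx;
    double c01 = b[sz] * (1 - tx) + b[sz + sx] * tx;
    double c11 = b[sz + sy] * (1 - tx) + b[sz + sy + sx] * tx;
    double c0 = c00 * (1 - ty) + c10 * ty;
    double c1 = c01 * (1 - ty) + c11 * ty;
    out[p] = c0 * (1 - tz) + c1 * tz;
    inside[p] = true;
  }
  return List::create(_["values"] = out, _["inside"] = inside);
}

// Minimum Euclidean distance from each query point (Nx2) to a 2-D point set (Mx2).
// [[Rcpp::export(name = ".min_dist2d_cpp")]]
NumericVector min_dist2d_cpp(NumericMatrix query, NumericMatrix pts) {
  const int n = query.nrow(), m = pts.nrow();
  NumericVector out(n);
  std::vector<double> px(m), py(m);
  for (int j = 0; j < m; ++j) { px[j] = pts(j, 0); py[j] = pts(j, 1); }
  for (int i = 0; i < n; ++i) {
    double qx = query(i, 0), qy = query(i, 1), best = R_PosInf;
    for (int j = 0; j < m; ++j) {
      double dx = qx - px[j], dy = qy - py[j];
      double d2 = dx * dx + dy * dy;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Even-odd point-in-polygon test for a batch of 2-D points.
// [[Rcpp::export(name = ".point_in_polygon_cpp")]]
LogicalVector point_in_polygon_cpp(NumericMatrix query, NumericMatrix poly) {
  const int n = query.nrow(), m = poly.nrow();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) {
    double qx = query(i, 0), qy = query(i, 1);
    bool in = false;
    for (int j = 0, k = m - 1; j < m; k = j++) {
      double xj = poly(j, 0), yj = poly(j, 1), xk = poly(k, 0), yk = poly(k, 1);
      if (((yj > qy) != (yk > qy)) &&
          (qx < (xk - xj) * (qy - yj) / (yk - yj) + xj))
        in = !in;
    }
    out[i] = in;
  }
  return out;
}

// Voxelize a closed triangulated surface by x-ray parity counting.
// verts: Nx3 mm, faces: Mx3 0-based vertex indices, grid: n[3] voxels with
// voxel centres origin + index*spacing. Returns logical array mask (voxel
// centre inside or on the surface). Ray origins are jittered by a tiny
// sub-voxel offset so rays do not pass exactly through triangle edges.
// [[Rcpp::export(name = ".voxelize_cpp")]]
LogicalVector voxelize_cpp(NumericMatrix verts, IntegerMatrix faces,
                           IntegerVector n, NumericVector spacing,
                           NumericVector origin) {
  const int nx = n[0], ny = n[1], nz = n[2];
  const int nf = faces.nrow();
  const double jy = 0.5e-6 * spacing[1], jz = 0.5e-6 * spacing[2];
  std::vector<std::vector<double> > cross((size_t)ny * nz);
  for (int f = 0; f < nf; ++f) {
    int i0 = faces(f, 0), i1 = faces(f, 1), i2 = faces(f, 2);
    double ax = verts(i0, 0), ay = verts(i0, 1), az = verts(i0, 2);
    double bx = verts(i1, 0), by = verts(i1, 1), bz = verts(i1, 2);
    double cx = verts(i2, 0), cy = verts(i2, 1), cz = verts(i2, 2);
    // projected (y,z) bounding box -> grid index range
    double ylo = std::min(ay, std::min(by, cy)), yhi = std::max(ay, std::max(by, cy));
    double zlo = std::min(az, std::min(bz, cz)), zhi = std::max(az, std::max(bz, cz));
    int j0 = (int)std::ceil((ylo - origin[1] - jy) / spacing[1]);
    int j1 = (int)std::floor((yhi - origin[1] - jy) / spacing[1]);
    int k0 = (int)std::ceil((zlo - origin[2] - jz) / spacing[2]);
    int k1 = (int)std::floor((zhi - origin[2] - jz) / spacing[2]);
    j0 = std::max(j0, 0); j1 = std::min(j1, ny - 1);
    k0 = std::max(k0, 0); k1 = std::min(k1, nz - 1);
    if (j0 > j1 || k0 > k1) continue;
    // 2*area of the (y,z) projection; zero means triangle parallel to the ray
    double det = (by - ay) * (cz - az) - (cy - ay) * (bz - az);
    if (det == 0) continue;
    for (int j = j0; j <= j1; ++j) {
      double py = origin[1] + j * spacing[1] + jy;
      for (int k = k0; k <= k1; ++k) {
        double pz = origin[2] + k * spacing[2] + jz;
        // solve [by-ay, cy-ay; bz-az, cz-az] [s;t] = [py-ay; pz-az]
        double s = ((py - ay) * (cz - az) - (cy - ay) * (pz - az)) / det;
        double t = ((by - ay) * (pz - az) - (py - ay) * (bz - az)) / det;
        if (s < 0 || t < 0 || s + t > 1) continue;
        double xcross = ax + s * (bx - ax) + t * (cx - ax);
        cross[(size_t)j + (size_t)ny * k].push_back(xcross);
      }
    }
  }
  LogicalVector mask((R_xlen_t)nx * ny * nz);
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      std::vector<double> &cs = cross[(size_t)j + (size_t)ny * k];
      if (cs.empty()) continue;
      std::sort(cs.begin(), cs.end());
      size_t nc = cs.size();
      // pair up crossings: inside between cs[0]..cs[1], cs[2]..cs[3], ...
      for (size_t c = 0; c + 1 < nc; c += 2) {
        int i0 = (int)std::ceil((cs[c] - origin[0]) / spacing[0] - 1e-9);
        int i1 = (int)std::floor((cs[c + 1] - origin[0]) / spacing[0] + 1e-9);
        i0 = std::max(i0, 0); i1 = std::min(i1, nx - 1);
        for (int i = i0; i <= i1; ++i)
          mask[(R_xlen_t)i + (R_xlen_t)nx * j + (R_xlen_t)nx * ny * k] = true;
      }
    }
  }
  return mask;
}

// For each point of A (Nx3) the distance to its nearest neighbour in B (Mx3).
// B is hashed into a uniform grid; shells of cells are scanned outward until
// no closer point can exist.
// [[Rcpp::export(name = ".nn_dist3d_cpp")]]
NumericVector nn_dist3d_cpp(NumericMatrix A, NumericMatrix B) {
  const int n = A.nrow(), m = B.nrow();
  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) { lo[d] = R_PosInf; hi[d] = R_NegInf; }
  for (int j = 0; j < m; ++j)
    for (int d = 0; d < 3; ++d) {
      lo[d] = std::min(lo[d], B(j, d));
      hi[d] = std::max(hi[d], B(j, d));
    }
  double vol = 1.0;
  for (int d = 0; d < 3; ++d) vol *= std::max(hi[d] - lo[d], 1e-9);
  double h = std::max(0.9 * std::cbrt(vol / m), 1e-6);
  int nc[3];
  for (int d = 0; d < 3; ++d)
    nc[d] = std::max(1, (int)std::floor((hi[d] - lo[d]) / h) + 1);
  const size_t ncells = (size_t)nc[0] * nc[1] * nc[2];
  std::vector<int> count(ncells + 1, 0);
  std::vector<int> cell(m);
  for (int j = 0; j < m; ++j) {
    int c[3];
    for (int d = 0; d < 3; ++d) {
      c[d] = (int)((B(j, d) - lo[d]) / h);
      c[d] = std::min(std::max(c[d], 0), nc[d] - 1);
    }
    cell[j] = c[0] + nc[0] * (c[1] + nc[1] * c[2]);
    count[cell[j] + 1]++;
  }
  for (size_t c = 1; c <= ncells; ++c) count[c] += count[c - 1];
  std::vector<int> bucket(m);
  {
    std::vector<int> fill(count.begin(), count.end() - 1);
    for (int j = 0; j < m; ++j) bucket[fill[cell[j]]++] = j;
  }
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double q[3] = {A(i, 0), A(i, 1), A(i, 2)};
    int qc[3];
    for (int d = 0; d < 3; ++d) {
      qc[d] = (int)std::floor((q[d] - lo[d]) / h);
      qc[d] = std::min(std::max(qc[d], 0), nc[d] - 1);
    }
    double best2 = R_PosInf;
    int max_rad = std::max(std::max(nc[0], nc[1]), nc[2]);
    for (int rad = 0; rad <= max_rad; ++rad) {
      if (rad > 0) {
        double shell_min = (rad - 1) * h;
        if (shell_min * shell_min > best2) break;
      }
      for (int dx = -rad; dx <= rad; ++dx) {
        int cx = qc[0] + dx;
        if (cx < 0 || cx >= nc[0]) continue;
        for (int dy = -rad; dy <= rad; ++dy) {
          int cy = qc[1] + dy;
          if (cy < 0 || cy >= nc[1]) continue;
          bool face = std::abs(dx) == rad || std::abs(dy) == rad;
          int step = face ? 1 : 2 * rad;
          if (step == 0) step = 1;
          for (int dz = -rad; dz <= rad; dz += step) {
            int cz = qc[2] + dz;
            if (cz < 0 || cz >= nc[2]) continue;
            size_t cc = (size_t)cx + nc[0] * ((size_t)cy + (size_t)nc[1] * cz);
            for (int b = count[cc]; b < count[cc + 1]; ++b) {
              int j = bucket[b];
              double ddx = q[0] - B(j, 0), ddy = q[1] - B(j, 1), ddz = q[2] - B(j, 2);
              double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
              if (d2 < best2) best2 = d2;
            }
          }
        }
      }
    }
    out[i] = std::sqrt(best2);
  }
  return out;
}

// Radial peak-search deformation of contour points on an edge map.
// edge: nx x ny image, node (i,j) at (x0 + i*sp, y0 + j*sp); pts: n x 2
// initialisation points; (cx, cy): ray origin (ellipse centroid); hw: half
// window in pixels. Each point moves along its ray to the strict local
// maximum (positive value; plateaus peak at their centre) nearest to its
// start; ties prefer the inward (negative) offset; no peak leaves the
// point in place.
// [[Rcpp::export(name = ".deform_cpp")]]
NumericMatrix deform_cpp(NumericMatrix edge, double x0, double y0, double sp,
                         NumericMatrix pts, double cx, double cy, int hw) {
  const int nx = edge.nrow(), ny = edge.ncol();
  const int n = pts.nrow(), w = 2 * hw + 1;
  NumericMatrix out(n, 2);
  std::vector<double> prof(w);
  for (int i = 0; i < n; ++i) {
    double px = pts(i, 0), py = pts(i, 1);
    double dx = px - cx, dy = py - cy;
    double len = std::sqrt(dx * dx + dy * dy);
    out(i, 0) = px; out(i, 1) = py;
    if (len < 1e-12) continue;
    dx /= len; dy /= len;
    for (int s = -hw; s <= hw; ++s) {
      double fx = (px + s * sp * dx - x0) / sp;
      double fy = (py + s * sp * dy - y0) / sp;
      double v = 0.0;
      if (fx >= 0 && fy >= 0 && fx <= nx - 1 && fy <= ny - 1) {
        int i0 = std::min((int)std::floor(fx), nx - 2);
        int j0 = std::min((int)std::floor(fy), ny - 2);
        double tx = fx - i0, ty = fy - j0;
        v = edge(i0, j0) * (1 - tx) * (1 - ty) + edge(i0 + 1, j0) * tx * (1 - ty) +
            edge(i0, j0 + 1) * (1 - tx) * ty + edge(i0 + 1, j0 + 1) * tx * ty;
      }
      prof[s + hw] = v;
    }
    // run-length scan for strict local maxima (plateau centres)
    int best = INT_MAX; // offset in samples from centre
    int r0 = 0;
    while (r0 < w) {
      int r1 = r0;
      while (r1 + 1 < w && prof[r1 + 1] == prof[r0]) ++r1;
      bool left_ok = r0 > 0 && prof[r0 - 1] < prof[r0];
      bool right_ok = r1 + 1 < w && prof[r1 + 1] < prof[r0];
      if (left_ok && right_ok && prof[r0] > 0) {
        int centre = (r0 + r1) / 2 - hw;
        bool better = std::abs(centre) < std::abs(best) ||
          (std::abs(centre) == std::abs(best) && centre < best);
        if (better) best = centre;
      }
      r0 = r1 + 1;
    }
    if (best != INT_MAX) {
      out(i, 0) = px + best * sp * dx;
      out(i, 1) = py + best * sp * dy;
    }
  }
  return out;
}
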