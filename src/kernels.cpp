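// Voxel-grid kernels: connected components, cross-shaped morphology, and
// rigid/affine resampling. Grids are R arrays in column-major order with
// dimensions (nx, ny, nz); all indexing here is 0-based.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Keep only the largest 26-connected foreground component.
// [[Rcpp::export(name = ".largest_component_26")]]
LogicalVector largest_component_26(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dim");
  std::vector<int> label(n, 0);
  std::vector<R_xlen_t> stack;
  int ncomp = 0;
  R_xlen_t bestSize = 0;
  int bestLab = 0;

  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  for (R_xlen_t seed = 0; seed < n; ++seed) {
    if (!mask[seed] || label[seed]) continue;
    ++ncomp;
    R_xlen_t size = 0;
    stack.clear();
    stack.push_back(seed);
    label[seed] = ncomp;
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      ++size;
      int x = (int)(v % nx), y = (int)((v / nx) % ny), z = (int)(v / sz);
      for (int dz = -1; dz <= 1; ++dz) {
        int zz = z + dz; if (zz < 0 || zz >= nz) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int yy = y + dy; if (yy < 0 || yy >= ny) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int xx = x + dx; if (xx < 0 || xx >= nx) continue;
            R_xlen_t w = xx * sx + yy * sy + zz * sz;
            if (mask[w] && !label[w]) { label[w] = ncomp; stack.push_back(w); }
          }
        }
      }
    }
    if (size > bestSize) { bestSize = size; bestLab = ncomp; }
  }
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = (label[i] == bestLab);
  out.attr("dim") = dim;
  return out;
}

// Count 26-connected foreground components (used by mask validation).
// [[Rcpp::export(name = ".count_components_26")]]
int count_components_26(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<char> seen(n, 0);
  std::vector<R_xlen_t> stack;
  int ncomp = 0;
  const R_xlen_t sz = (R_xlen_t)nx * ny;
  for (R_xlen_t seed = 0; seed < n; ++seed) {
    if (!mask[seed] || seen[seed]) continue;
    ++ncomp;
    stack.clear(); stack.push_back(seed); seen[seed] = 1;
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      int x = (int)(v % nx), y = (int)((v / nx) % ny), z = (int)(v / sz);
      for (int dz = -1; dz <= 1; ++dz) {
        int zz = z + dz; if (zz < 0 || zz >= nz) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int yy = y + dy; if (yy < 0 || yy >= ny) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int xx = x + dx; if (xx < 0 || xx >= nx) continue;
            R_xlen_t w = xx + (R_xlen_t)yy * nx + (R_xlen_t)zz * sz;
            if (mask[w] && !seen[w]) { seen[w] = 1; stack.push_back(w); }
          }
        }
      }
    }
  }
  return ncomp;
}

// Morphological dilation (op = 1) or erosion (op = 0) with the 6-neighbour
// cross, i.e. the discrete ball of radius 1 voxel. Out-of-grid is background.
// [[Rcpp::export(name = ".morph_cross")]]
LogicalVector morph_cross(LogicalVector mask, IntegerVector dim, int op) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n);
  const R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t v = x + (R_xlen_t)y * sy + (R_xlen_t)z * sz;
        int c = mask[v];
        int xm = (x > 0) ? (int)mask[v - 1] : 0;
        int xp = (x < nx - 1) ? (int)mask[v + 1] : 0;
        int ym = (y > 0) ? (int)mask[v - sy] : 0;
        int yp = (y < ny - 1) ? (int)mask[v + sy] : 0;
        int zm = (z > 0) ? (int)mask[v - sz] : 0;
        int zp = (z < nz - 1) ? (int)mask[v + sz] : 0;
        if (op == 1)
          out[v] = c || xm || xp || ym || yp || zm || zp;
        else
          out[v] = c && xm && xp && ym && yp && zm && zp;
      }
  out.attr("dim") = dim;
  return out;
}

// Resample a volume onto an output grid. For output voxel (i,j,k) the source
// continuous 0-based index is  s = M %*% c(i,j,k) + off.  linear = trilinear
// interpolation, otherwise nearest neighbour; outside samples = background.
// [[Rcpp::export(name = ".resample_affine")]]
NumericVector resample_affine(NumericVector vol, IntegerVector dim,
                              IntegerVector out_dim, NumericMatrix M,
                              NumericVector off, bool linear,
                              double background) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int ox = out_dim[0], oy = out_dim[1], oz = out_dim[2];
  const R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;
  NumericVector out((R_xlen_t)ox * oy * oz);
  const double m00 = M(0,0), m01 = M(0,1), m02 = M(0,2);
  const double m10 = M(1,0), m11 = M(1,1), m12 = M(1,2);
  const double m20 = M(2,0), m21 = M(2,1), m22 = M(2,2);
  R_xlen_t o = 0;
  for (int k = 0; k < oz; ++k)
    for (int j = 0; j < oy; ++j) {
      double bx = m01 * j + m02 * k + off[0];
      double by = m11 * j + m12 * k + off[1];
      double bz = m21 * j + m22 * k + off[2];
      for (int i = 0; i < ox; ++i, ++o) {
        double xs = m00 * i + bx, ys = m10 * i + by, zs = m20 * i + bz;
        if (linear) {
          int x0 = (int)std::floor(xs), y0 = (int)std::floor(ys),
              z0 = (int)std::floor(zs);
          if (x0 < -1 || y0 < -1 || z0 < -1 ||
              x0 > nx - 1 || y0 > ny - 1 || z0 > nz - 1) {
            out[o] = background;
            continue;
          }
          double fx = xs - x0, fy = ys - y0, fz = zs - z0;
          double acc = 0;
          for (int dz = 0; dz <= 1; ++dz) {
            int z1 = z0 + dz;
            double wz = dz ? fz : 1 - fz;
            if (wz == 0) continue;
            for (int dy = 0; dy <= 1; ++dy) {
              int y1 = y0 + dy;
              double wy = dy ? fy : 1 - fy;
              if (wy == 0) continue;
              for (int dx = 0; dx <= 1; ++dx) {
                int x1 = x0 + dx;
                double wx = dx ? fx : 1 - fx;
                if (wx == 0) continue;
                double val;
                if (x1 < 0 || y1 < 0 || z1 < 0 || x1 >= nx || y1 >= ny || z1 >= nz)
                  val = background;
                else
                  val = vol[x1 + (R_xlen_t)y1 * sy + (R_xlen_t)z1 * sz];
                acc += wx * wy * wz * val;
              }
            }
          }
          out[o] = acc;
        } else {
          int x1 = (int)std::lround(xs), y1 = (int)std::lround(ys),
              z1 = (int)std::lround(zs);
          if (x1 < 0 || y1 < 0 || z1 < 0 || x1 >= nx || y1 >= ny || z1 >= nz)
            out[o] = background;
          else
            out[o] = vol[x1 + (R_xlen_t)y1 * sy + (R_xlen_t)z1 * sz];
        }
      }
    }
  out.attr("dim") = out_dim;
  return out;
}
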