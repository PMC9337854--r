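#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Arrays are R arrays with dim = (nz, ny, nx): first index varies fastest.
// All physical geometry is computed in micrometres from (z,y,x) voxel sizes.

static inline R_xlen_t idx3(int z, int y, int x, int nz, int ny) {
  return (R_xlen_t)z + (R_xlen_t)nz * ((R_xlen_t)y + (R_xlen_t)ny * (R_xlen_t)x);
}

// Separable 1-D convolution along one axis (0 = z, 1 = y, 2 = x) with
// reflect padding. Kernel is assumed odd-length and centred.
// [[Rcpp::export]]
NumericVector cpp_conv_axis(NumericVector vol, IntegerVector dim,
                            NumericVector kernel, int axis) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  int n[3] = {nz, ny, nx};
  int klen = kernel.size(), khalf = klen / 2;
  int len = n[axis];
  NumericVector out(vol.size());
  std::vector<double> line(len), res(len);

  R_xlen_t stride;
  if (axis == 0) stride = 1;
  else if (axis == 1) stride = nz;
  else stride = (R_xlen_t)nz * ny;

  int no1 = (axis == 0) ? ny : nz;
  int no2 = (axis == 2) ? ny : nx;

  for (int a = 0; a < no1; ++a) {
    for (int b = 0; b < no2; ++b) {
      R_xlen_t base;
      if (axis == 0)      base = idx3(0, a, b, nz, ny);
      else if (axis == 1) base = idx3(a, 0, b, nz, ny);
      else                base = idx3(a, b, 0, nz, ny);
      for (int i = 0; i < len; ++i) line[i] = vol[base + stride * i];
      for (int i = 0; i < len; ++i) {
        double s = 0.0;
        for (int k = 0; k < klen; ++k) {
          int j = i + k - khalf;
          if (j < 0) j = -j - 1;                 // reflect
          if (j >= len) j = 2 * len - j - 1;
          if (j < 0) j = 0;
          if (j >= len) j = len - 1;             // degenerate short axes
          s += line[j] * kernel[k];
        }
        res[i] = s;
      }
      for (int i = 0; i < len; ++i) out[base + stride * i] = res[i];
    }
  }
  out.attr("dim") = dim;
  return out;
}

// Running min or max filter along one axis with half-width r (box).
// [[Rcpp::export]]
NumericVector cpp_minmax_axis(NumericVector vol, IntegerVector dim,
                              int r, int axis, bool take_max) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  int n[3] = {nz, ny, nx};
  int len = n[axis];
  NumericVector out(vol.size());
  std::vector<double> line(len), res(len);

  R_xlen_t stride;
  if (axis == 0) stride = 1;
  else if (axis == 1) stride = nz;
  else stride = (R_xlen_t)nz * ny;
  int no1 = (axis == 0) ? ny : nz;
  int no2 = (axis == 2) ? ny : nx;

  for (int a = 0; a < no1; ++a) {
    for (int b = 0; b < no2; ++b) {
      R_xlen_t base;
      if (axis == 0)      base = idx3(0, a, b, nz, ny);
      else if (axis == 1) base = idx3(a, 0, b, nz, ny);
      else                base = idx3(a, b, 0, nz, ny);
      for (int i = 0; i < len; ++i) line[i] = vol[base + stride * i];
      for (int i = 0; i < len; ++i) {
        int lo = std::max(0, i - r), hi = std::min(len - 1, i + r);
        double v = line[lo];
        for (int j = lo + 1; j <= hi; ++j)
          v = take_max ? std::max(v, line[j]) : std::min(v, line[j]);
        res[i] = v;
      }
      for (int i = 0; i < len; ++i) out[base + stride * i] = res[i];
    }
  }
  out.attr("dim") = dim;
  return out;
}

// 6-connected component labeling of a binary mask; labels 1..k in first-voxel
// scan order (deterministic).
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  R_xlen_t ntot = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(ntot, 0);
  int next = 0;
  std::vector<R_xlen_t> stack;
  const int dz[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dx[6] = {0, 0, 0, 0, 1, -1};

  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t i = idx3(z, y, x, nz, ny);
        if (!mask[i] || lab[i] != 0) continue;
        ++next;
        lab[i] = next;
        stack.clear();
        stack.push_back(i);
        while (!stack.empty()) {
          R_xlen_t c = stack.back(); stack.pop_back();
          int cz = (int)(c % nz);
          int cy = (int)((c / nz) % ny);
          int cx = (int)(c / ((R_xlen_t)nz * ny));
          for (int k = 0; k < 6; ++k) {
            int zz = cz + dz[k], yy = cy + dy[k], xx = cx + dx[k];
            if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
              continue;
            R_xlen_t j = idx3(zz, yy, xx, nz, ny);
            if (mask[j] && lab[j] == 0) { lab[j] = next; stack.push_back(j); }
          }
        }
      }
  lab.attr("dim") = dim;
  return lab;
}

// Strict-or-equal local maxima over the 26-neighborhood, value > thresh.
// Returns 1-based linear indices.
// [[Rcpp::export]]
IntegerVector cpp_local_maxima(NumericVector vol, IntegerVector dim,
                               double thresh) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<int> hits;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t i = idx3(z, y, x, nz, ny);
        double v = vol[i];
        if (!(v > thresh)) continue;
        bool ismax = true;
        for (int dx = -1; dx <= 1 && ismax; ++dx)
          for (int dy = -1; dy <= 1 && ismax; ++dy)
            for (int dz = -1; dz <= 1 && ismax; ++dz) {
              if (!dx && !dy && !dz) continue;
              int zz = z + dz, yy = y + dy, xx = x + dx;
              if (zz < 0 || zz >= nz || yy < 0 || yy >= ny ||
                  xx < 0 || xx >= nx) continue;
              if (vol[idx3(zz, yy, xx, nz, ny)] > v) ismax = false;
            }
        if (ismax) hits.push_back((int)(i + 1));
      }
  return wrap(hits);
}

static inline double tri_area(const double a[3], const double b[3],
                              const double c[3]) {
  double u[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  double v[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
  double cx = u[1] * v[2] - u[2] * v[1];
  double cy = u[2] * v[0] - u[0] * v[2];
  double cz = u[0] * v[1] - u[1] * v[0];
  return 0.5 * std::sqrt(cx * cx + cy * cy + cz * cz);
}

// Total area of the level-set isosurface of a scalar field, by marching
// tetrahedra (each cube cell split into 6 tetrahedra around the main
// diagonal). Vertices sit at voxel centres scaled by the (z,y,x) voxel size,
// so anisotropy is handled exactly. Field values outside the array are taken
// as below the level (closed surfaces at the boundary).
// [[Rcpp::export]]
double cpp_isosurface_area(NumericVector field, IntegerVector dim,
                           NumericVector voxel, double level) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  double vz = voxel[0], vy = voxel[1], vx = voxel[2];
  // corner offsets in (z,y,x); corner index bit0=x, bit1=y, bit2=z
  const int co[8][3] = {
    {0,0,0},{0,0,1},{0,1,0},{0,1,1},{1,0,0},{1,0,1},{1,1,0},{1,1,1}};
  // six tetrahedra sharing diagonal 0-7
  const int tets[6][4] = {
    {0,1,3,7},{0,3,2,7},{0,2,6,7},{0,6,4,7},{0,4,5,7},{0,5,1,7}};
  double total = 0.0;

  // pad by one cell on every side so boundary-touching regions close
  for (int x = -1; x < nx; ++x)
    for (int y = -1; y < ny; ++y)
      for (int z = -1; z < nz; ++z) {
        double f[8];
        double p[8][3];
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int zz = z + co[c][0], yy = y + co[c][1], xx = x + co[c][2];
          double val;
          if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
            val = level - 1.0; // outside: below level
          else
            val = field[idx3(zz, yy, xx, nz, ny)];
          f[c] = val - level;
          if (f[c] > 0) any_in = true; else any_out = true;
          p[c][0] = zz * vz; p[c][1] = yy * vy; p[c][2] = xx * vx;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          const int *T = tets[t];
          int in[4], nin = 0, out[4], nout = 0;
          for (int k = 0; k < 4; ++k) {
            if (f[T[k]] > 0) in[nin++] = T[k]; else out[nout++] = T[k];
          }
          if (nin == 0 || nin == 4) continue;
          auto interp = [&](int A, int B, double q[3]) {
            double tt = f[A] / (f[A] - f[B]);
            for (int d = 0; d < 3; ++d)
              q[d] = p[A][d] + tt * (p[B][d] - p[A][d]);
          };
          if (nin == 1 || nin == 3) {
            int apex = (nin == 1) ? in[0] : out[0];
            int oth[3], m = 0;
            for (int k = 0; k < 4; ++k)
              if (T[k] != apex) oth[m++] = T[k];
            double q0[3], q1[3], q2[3];
            interp(apex, oth[0], q0);
            interp(apex, oth[1], q1);
            interp(apex, oth[2], q2);
            total += tri_area(q0, q1, q2);
          } else { // 2 in, 2 out -> quad
            double qac[3], qad[3], qbc[3], qbd[3];
            interp(in[0], out[0], qac);
            interp(in[0], out[1], qad);
            interp(in[1], out[0], qbc);
            interp(in[1], out[1], qbd);
            total += tri_area(qac, qad, qbd) + tri_area(qac, qbd, qbc);
          }
        }
      }
  return total;
}
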