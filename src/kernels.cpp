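#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Column-major 3D indexing throughout: linear = i + nx*(j + ny*k), 0-based.

static inline double trilinear(const double *v, int nx, int ny, int nz,
                               double x, double y, double z, bool *ok) {
  if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1) {
    *ok = false;
    return 0.0;
  }
  *ok = true;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  if (x0 == nx - 1) x0--;
  if (y0 == ny - 1) y0--;
  if (z0 == nz - 1) z0--;
  if (x0 < 0) x0 = 0;
  if (y0 < 0) y0 = 0;
  if (z0 < 0) z0 = 0;
  double fx = x - x0, fy = y - y0, fz = z - z0;
  const size_t sx = 1, sy = (size_t)nx, sz = (size_t)nx * ny;
  const double *p = v + x0 * sx + y0 * sy + z0 * sz;
  double c00 = p[0] * (1 - fx) + p[sx] * fx;
  double c10 = p[sy] * (1 - fx) + p[sx + sy] * fx;
  double c01 = p[sz] * (1 - fx) + p[sx + sz] * fx;
  double c11 = p[sy + sz] * (1 - fx) + p[sx + sy + sz] * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

static inline double nearestv(const double *v, int nx, int ny, int nz,
                              double x, double y, double z, bool *ok) {
  int xi = (int)std::lround(x), yi = (int)std::lround(y), zi = (int)std::lround(z);
  if (xi < 0 || yi < 0 || zi < 0 || xi >= nx || yi >= ny || zi >= nz) {
    *ok = false;
    return 0.0;
  }
  *ok = true;
  return v[xi + (size_t)nx * (yi + (size_t)ny * zi)];
}

// Resample a moving volume onto a fixed grid.
// vox2world: 4x4, fixed voxel index (0-based) -> fixed world (mm)
// world2mov: 4x4, fixed world (after adding the displacement) -> moving voxel index
// field: optional pull-back displacement (mm) on the fixed grid, dim c(outdim, 3)
// interp: 0 nearest, 1 trilinear (outside -> 0), 2 trilinear with clamping
// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector mov, IntegerVector movdim,
                           IntegerVector outdim, NumericMatrix vox2world,
                           NumericMatrix world2mov, Nullable<NumericVector> field,
                           int interp) {
  const int nx = movdim[0], ny = movdim[1], nz = movdim[2];
  const int ox = outdim[0], oy = outdim[1], oz = outdim[2];
  const double *mv = REAL(mov);
  NumericVector out((R_xlen_t)ox * oy * oz);
  double *o = REAL(out);
  const double *u = nullptr;
  if (field.isNotNull()) u = REAL(NumericVector(field));
  double A[12], B[12];
  for (int r = 0; r < 3; r++)
    for (int c = 0; c < 4; c++) {
      A[r * 4 + c] = vox2world(r, c);
      B[r * 4 + c] = world2mov(r, c);
    }
  const size_t nvox = (size_t)ox * oy * oz;
  size_t idx = 0;
  for (int k = 0; k < oz; k++)
    for (int j = 0; j < oy; j++)
      for (int i = 0; i < ox; i++, idx++) {
        double wx = A[0] * i + A[1] * j + A[2] * k + A[3];
        double wy = A[4] * i + A[5] * j + A[6] * k + A[7];
        double wz = A[8] * i + A[9] * j + A[10] * k + A[11];
        if (u) {
          wx += u[idx];
          wy += u[idx + nvox];
          wz += u[idx + 2 * nvox];
        }
        double mx = B[0] * wx + B[1] * wy + B[2] * wz + B[3];
        double my = B[4] * wx + B[5] * wy + B[6] * wz + B[7];
        double mz = B[8] * wx + B[9] * wy + B[10] * wz + B[11];
        bool ok;
        if (interp == 2) {
          mx = std::min((double)nx - 1, std::max(0.0, mx));
          my = std::min((double)ny - 1, std::max(0.0, my));
          mz = std::min((double)nz - 1, std::max(0.0, mz));
        }
        o[idx] = (interp >= 1) ? trilinear(mv, nx, ny, nz, mx, my, mz, &ok)
                               : nearestv(mv, nx, ny, nz, mx, my, mz, &ok);
        if (!ok) o[idx] = 0.0;
      }
  out.attr("dim") = outdim;
  return out;
}

// Joint histogram of two equally-shaped volumes over a mask.
// [[Rcpp::export]]
NumericMatrix cpp_joint_hist(NumericVector a, NumericVector b, IntegerVector mask,
                             int bins, double amin, double amax, double bmin,
                             double bmax) {
  NumericMatrix h(bins, bins);
  const double *pa = REAL(a), *pb = REAL(b);
  const int *pm = INTEGER(mask);
  const double asc = (amax > amin) ? bins / (amax - amin) : 0.0;
  const double bsc = (bmax > bmin) ? bins / (bmax - bmin) : 0.0;
  const R_xlen_t n = a.size();
  for (R_xlen_t i = 0; i < n; i++) {
    if (!pm[i]) continue;
    int ia = (int)((pa[i] - amin) * asc);
    int ib = (int)((pb[i] - bmin) * bsc);
    if (ia < 0 || ib < 0) continue;
    if (ia >= bins) ia = bins - 1;
    if (ib >= bins) ib = bins - 1;
    h(ia, ib) += 1.0;
  }
  return h;
}

// Mutual information (nats) between a fixed volume and an affinely mapped
// moving volume, evaluated only at masked fixed voxels whose mapped position
// falls inside the moving volume. map: 4x4 fixed voxel idx -> moving voxel idx.
// min_count: if fewer masked voxels than this map inside the moving volume,
// the overlap is considered broken and a large negative value is returned,
// so the optimizer cannot gain similarity by pushing the images apart.
// [[Rcpp::export]]
double cpp_mi_affine(NumericVector fixedv, IntegerVector fdim, NumericVector mov,
                     IntegerVector mdim, IntegerVector mask, NumericMatrix map,
                     int bins, double fmin, double fmax, double mmin, double mmax,
                     double min_count) {
  const int fx = fdim[0], fy = fdim[1], fz = fdim[2];
  const int nx = mdim[0], ny = mdim[1], nz = mdim[2];
  const double *fv = REAL(fixedv), *mv = REAL(mov);
  const int *pm = INTEGER(mask);
  double M[12];
  for (int r = 0; r < 3; r++)
    for (int c = 0; c < 4; c++) M[r * 4 + c] = map(r, c);
  std::vector<double> h((size_t)bins * bins, 0.0);
  const double fsc = (fmax > fmin) ? bins / (fmax - fmin) : 0.0;
  const double msc = (mmax > mmin) ? bins / (mmax - mmin) : 0.0;
  double total = 0.0;
  size_t idx = 0;
  for (int k = 0; k < fz; k++)
    for (int j = 0; j < fy; j++)
      for (int i = 0; i < fx; i++, idx++) {
        if (!pm[idx]) continue;
        double mx = M[0] * i + M[1] * j + M[2] * k + M[3];
        double my = M[4] * i + M[5] * j + M[6] * k + M[7];
        double mz = M[8] * i + M[9] * j + M[10] * k + M[11];
        bool ok;
        double s = trilinear(mv, nx, ny, nz, mx, my, mz, &ok);
        if (!ok) continue;
        int ia = (int)((fv[idx] - fmin) * fsc);
        int ib = (int)((s - mmin) * msc);
        if (ia < 0) ia = 0;
        if (ib < 0) ib = 0;
        if (ia >= bins) ia = bins - 1;
        if (ib >= bins) ib = bins - 1;
        h[(size_t)ia + (size_t)bins * ib] += 1.0;
        total += 1.0;
      }
  if (total < 2 || total < min_count) return -1e10;
  std::vector<double> pa(bins, 0.0), pb(bins, 0.0);
  for (int ib = 0; ib < bins; ib++)
    for (int ia = 0; ia < bins; ia++) {
      double p = h[(size_t)ia + (size_t)bins * ib] / total;
      pa[ia] += p;
      pb[ib] += p;
    }
  double mi = 0.0;
  for (int ib = 0; ib < bins; ib++)
    for (int ia = 0; ia < bins; ia++) {
      double p = h[(size_t)ia + (size_t)bins * ib] / total;
      if (p > 0) mi += p * std::log(p / (pa[ia] * pb[ib]));
    }
  return mi;
}

static void neighbour_offsets(int connectivity, std::vector<int> &dx,
                              std::vector<int> &dy, std::vector<int> &dz) {
  dx.clear(); dy.clear(); dz.clear();
  for (int a = -1; a <= 1; a++)
    for (int b = -1; b <= 1; b++)
      for (int c = -1; c <= 1; c++) {
        int m = std::abs(a) + std::abs(b) + std::abs(c);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        dx.push_back(a); dy.push_back(b); dz.push_back(c);
      }
}

// Connected components of a binary volume. Components are numbered from 1 in
// raster order of their first (lowest linear index) voxel.
// [[Rcpp::export]]
IntegerVector cpp_label3d(IntegerVector mask, IntegerVector dims, int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n);
  const int *pm = INTEGER(mask);
  int *pl = INTEGER(lab);
  std::vector<int> dx, dy, dz;
  neighbour_offsets(connectivity, dx, dy, dz);
  const int nn = (int)dx.size();
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; s++) {
    if (!pm[s] || pl[s]) continue;
    next++;
    pl[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int i = (int)(v % nx), j = (int)((v / nx) % ny), k = (int)(v / ((R_xlen_t)nx * ny));
      for (int q = 0; q < nn; q++) {
        int ii = i + dx[q], jj = j + dy[q], kk = k + dz[q];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
        R_xlen_t w = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
        if (pm[w] && !pl[w]) {
          pl[w] = next;
          stack.push_back(w);
        }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// Binary dilation (iters passes) with a 6/18/26-connected structuring element.
// [[Rcpp::export]]
IntegerVector cpp_dilate(IntegerVector mask, IntegerVector dims, int connectivity,
                         int iters) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<int> dx, dy, dz;
  neighbour_offsets(connectivity, dx, dy, dz);
  const int nn = (int)dx.size();
  IntegerVector cur = clone(mask);
  for (int it = 0; it < iters; it++) {
    IntegerVector nxt = clone(cur);
    const int *pc = INTEGER(cur);
    int *pn = INTEGER(nxt);
    R_xlen_t v = 0;
    for (int k = 0; k < nz; k++)
      for (int j = 0; j < ny; j++)
        for (int i = 0; i < nx; i++, v++) {
          if (pc[v]) continue;
          for (int q = 0; q < nn; q++) {
            int ii = i + dx[q], jj = j + dy[q], kk = k + dz[q];
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
              continue;
            if (pc[ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk)]) {
              pn[v] = 1;
              break;
            }
          }
        }
    cur = nxt;
  }
  cur.attr("dim") = dims;
  return cur;
}

// Binary erosion; voxels outside the volume count as background.
// [[Rcpp::export]]
IntegerVector cpp_erode(IntegerVector mask, IntegerVector dims, int connectivity,
                        int iters) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<int> dx, dy, dz;
  neighbour_offsets(connectivity, dx, dy, dz);
  const int nn = (int)dx.size();
  IntegerVector cur = clone(mask);
  for (int it = 0; it < iters; it++) {
    IntegerVector nxt = clone(cur);
    const int *pc = INTEGER(cur);
    int *pn = INTEGER(nxt);
    R_xlen_t v = 0;
    for (int k = 0; k < nz; k++)
      for (int j = 0; j < ny; j++)
        for (int i = 0; i < nx; i++, v++) {
          if (!pc[v]) continue;
          for (int q = 0; q < nn; q++) {
            int ii = i + dx[q], jj = j + dy[q], kk = k + dz[q];
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz ||
                !pc[ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk)]) {
              pn[v] = 0;
              break;
            }
          }
        }
    cur = nxt;
  }
  cur.attr("dim") = dims;
  return cur;
}

// 1D convolution along one axis of a 3D array with an odd, centred kernel.
// Boundary handling renormalises by the in-bounds kernel mass, so constant
// inputs are preserved exactly.
// [[Rcpp::export]]
NumericVector cpp_conv_axis(NumericVector arr, IntegerVector dims,
                            NumericVector kernel, int axis) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int kl = kernel.size();
  const int h = kl / 2;
  const double *ka = REAL(kernel);
  const double *in = REAL(arr);
  NumericVector out((R_xlen_t)nx * ny * nz);
  double *o = REAL(out);
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  R_xlen_t stride;
  int nlen;
  if (axis == 0) { stride = sx; nlen = nx; }
  else if (axis == 1) { stride = sy; nlen = ny; }
  else { stride = sz; nlen = nz; }
  R_xlen_t v = 0;
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++, v++) {
        int pos = (axis == 0) ? i : (axis == 1) ? j : k;
        double acc = 0.0, wsum = 0.0;
        int lo = std::max(-h, -pos), hi = std::min(h, nlen - 1 - pos);
        for (int q = lo; q <= hi; q++) {
          double w = ka[q + h];
          acc += w * in[v + (R_xlen_t)q * stride];
          wsum += w;
        }
        o[v] = (wsum > 0) ? acc / wsum : 0.0;
      }
  out.attr("dim") = dims;
  return out;
}
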