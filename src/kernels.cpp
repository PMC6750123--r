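#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Trilinear sample of a 3D grid at continuous 0-based voxel coordinates.
// Points outside [0, n-1] on any axis are "outside" and yield 0.
static inline double tri_sample(const double* v, int nx, int ny, int nz,
                                double x, double y, double z, bool& inside) {
  if (x < 0.0 || y < 0.0 || z < 0.0 ||
      x > nx - 1.0 || y > ny - 1.0 || z > nz - 1.0) {
    inside = false;
    return 0.0;
  }
  inside = true;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  if (x0 > nx - 2) x0 = nx - 2; if (x0 < 0) x0 = 0;
  if (y0 > ny - 2) y0 = ny - 2; if (y0 < 0) y0 = 0;
  if (z0 > nz - 2) z0 = nz - 2; if (z0 < 0) z0 = 0;
  int x1 = x0 + 1 < nx ? x0 + 1 : x0;
  int y1 = y0 + 1 < ny ? y0 + 1 : y0;
  int z1 = z0 + 1 < nz ? z0 + 1 : z0;
  double fx = x - x0, fy = y - y0, fz = z - z0;
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  const double* p000 = v + x0 * sx + y0 * sy + z0 * sz;
  double c000 = p000[0];
  double c100 = v[x1 * sx + y0 * sy + z0 * sz];
  double c010 = v[x0 * sx + y1 * sy + z0 * sz];
  double c110 = v[x1 * sx + y1 * sy + z0 * sz];
  double c001 = v[x0 * sx + y0 * sy + z1 * sz];
  double c101 = v[x1 * sx + y0 * sy + z1 * sz];
  double c011 = v[x0 * sx + y1 * sy + z1 * sz];
  double c111 = v[x1 * sx + y1 * sy + z1 * sz];
  double c00 = c000 * (1 - fx) + c100 * fx;
  double c10 = c010 * (1 - fx) + c110 * fx;
  double c01 = c001 * (1 - fx) + c101 * fx;
  double c11 = c011 * (1 - fx) + c111 * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// Resample src onto an output grid. M is a 4x4 matrix mapping 0-based output
// voxel indices to 0-based src voxel indices (homogeneous, last row 0 0 0 1).
// [[Rcpp::export]]
NumericVector c_resample_trilinear(NumericVector src, IntegerVector sdim,
                                   IntegerVector odim, NumericMatrix M) {
  int snx = sdim[0], sny = sdim[1], snz = sdim[2];
  int onx = odim[0], ony = odim[1], onz = odim[2];
  NumericVector out((R_xlen_t)onx * ony * onz);
  const double* sv = src.begin();
  double* ov = out.begin();
  double m00 = M(0,0), m01 = M(0,1), m02 = M(0,2), m03 = M(0,3);
  double m10 = M(1,0), m11 = M(1,1), m12 = M(1,2), m13 = M(1,3);
  double m20 = M(2,0), m21 = M(2,1), m22 = M(2,2), m23 = M(2,3);
  R_xlen_t idx = 0;
  bool inside;
  for (int k = 0; k < onz; ++k) {
    for (int j = 0; j < ony; ++j) {
      double bx = m01 * j + m02 * k + m03;
      double by = m11 * j + m12 * k + m13;
      double bz = m21 * j + m22 * k + m23;
      for (int i = 0; i < onx; ++i, ++idx) {
        ov[idx] = tri_sample(sv, snx, sny, snz,
                             m00 * i + bx, m10 * i + by, m20 * i + bz, inside);
      }
    }
  }
  return out;
}

// Nearest-neighbour variant (binary masks): preserves the value set exactly.
// [[Rcpp::export]]
NumericVector c_resample_nearest(NumericVector src, IntegerVector sdim,
                                 IntegerVector odim, NumericMatrix M) {
  int snx = sdim[0], sny = sdim[1], snz = sdim[2];
  int onx = odim[0], ony = odim[1], onz = odim[2];
  NumericVector out((R_xlen_t)onx * ony * onz);
  const double* sv = src.begin();
  double* ov = out.begin();
  double m00 = M(0,0), m01 = M(0,1), m02 = M(0,2), m03 = M(0,3);
  double m10 = M(1,0), m11 = M(1,1), m12 = M(1,2), m13 = M(1,3);
  double m20 = M(2,0), m21 = M(2,1), m22 = M(2,2), m23 = M(2,3);
  R_xlen_t idx = 0;
  for (int k = 0; k < onz; ++k) {
    for (int j = 0; j < ony; ++j) {
      double bx = m01 * j + m02 * k + m03;
      double by = m11 * j + m12 * k + m13;
      double bz = m21 * j + m22 * k + m23;
      for (int i = 0; i < onx; ++i, ++idx) {
        long xi = (long)std::lround(m00 * i + bx);
        long yi = (long)std::lround(m10 * i + by);
        long zi = (long)std::lround(m20 * i + bz);
        if (xi < 0 || yi < 0 || zi < 0 || xi >= snx || yi >= sny || zi >= snz)
          ov[idx] = 0.0;
        else
          ov[idx] = sv[xi + yi * (R_xlen_t)snx + zi * (R_xlen_t)snx * sny];
      }
    }
  }
  return out;
}

// Fused ratio-image-uniformity accumulator: resamples `src` at the pulled-back
// position of every fixed voxel and accumulates the ratio fixed/src over the
// overlap domain (fixed > fixed_thresh AND sampled src > src_thresh, in-bounds).
// Returns c(n, sum_r, sum_r2). Avoids materializing the warped volume.
// [[Rcpp::export]]
NumericVector c_riu_accumulate(NumericVector fixed, IntegerVector fdim,
                               NumericVector src, IntegerVector sdim,
                               NumericMatrix M,
                               double fixed_thresh, double src_thresh) {
  int snx = sdim[0], sny = sdim[1], snz = sdim[2];
  int fnx = fdim[0], fny = fdim[1], fnz = fdim[2];
  const double* fv = fixed.begin();
  const double* sv = src.begin();
  double m00 = M(0,0), m01 = M(0,1), m02 = M(0,2), m03 = M(0,3);
  double m10 = M(1,0), m11 = M(1,1), m12 = M(1,2), m13 = M(1,3);
  double m20 = M(2,0), m21 = M(2,1), m22 = M(2,2), m23 = M(2,3);
  double n = 0.0, s = 0.0, ss = 0.0;
  R_xlen_t idx = 0;
  bool inside;
  for (int k = 0; k < fnz; ++k) {
    for (int j = 0; j < fny; ++j) {
      double bx = m01 * j + m02 * k + m03;
      double by = m11 * j + m12 * k + m13;
      double bz = m21 * j + m22 * k + m23;
      for (int i = 0; i < fnx; ++i, ++idx) {
        double f = fv[idx];
        if (f <= fixed_thresh) continue;
        double v = tri_sample(sv, snx, sny, snz,
                              m00 * i + bx, m10 * i + by, m20 * i + bz, inside);
        if (!inside || v <= src_thresh) continue;
        double r = f / v;
        n += 1.0; s += r; ss += r * r;
      }
    }
  }
  return NumericVector::create(n, s, ss);
}

// RIU accumulator over a precomputed sparse list of fixed voxels (0-based
// indices ii/jj/kk with intensities fvals, all already above the fixed
// threshold). Returns c(n, sum_r, sum_r2).
// [[Rcpp::export]]
NumericVector c_riu_accumulate_idx(NumericVector fvals, IntegerVector ii,
                                   IntegerVector jj, IntegerVector kk,
                                   NumericVector src, IntegerVector sdim,
                                   NumericMatrix M, double src_thresh) {
  int snx = sdim[0], sny = sdim[1], snz = sdim[2];
  const double* sv = src.begin();
  double m00 = M(0,0), m01 = M(0,1), m02 = M(0,2), m03 = M(0,3);
  double m10 = M(1,0), m11 = M(1,1), m12 = M(1,2), m13 = M(1,3);
  double m20 = M(2,0), m21 = M(2,1), m22 = M(2,2), m23 = M(2,3);
  double n = 0.0, s = 0.0, ss = 0.0;
  bool inside;
  R_xlen_t m = fvals.size();
  for (R_xlen_t t = 0; t < m; ++t) {
    double i = ii[t], j = jj[t], k = kk[t];
    double v = tri_sample(sv, snx, sny, snz,
                          m00 * i + m01 * j + m02 * k + m03,
                          m10 * i + m11 * j + m12 * k + m13,
                          m20 * i + m21 * j + m22 * k + m23, inside);
    if (!inside || v <= src_thresh) continue;
    double r = fvals[t] / v;
    n += 1.0; s += r; ss += r * r;
  }
  return NumericVector::create(n, s, ss);
}

// Separable Gaussian smoothing, kernel truncated at 3 sigma, edges replicated.
// sigma in voxels; sigma <= 0 returns a copy.
// [[Rcpp::export]]
NumericVector c_smooth_gaussian(NumericVector src, IntegerVector dims,
                                double sigma) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  std::copy(src.begin(), src.end(), out.begin());
  if (sigma <= 0) return out;
  int rad = (int)std::ceil(3.0 * sigma);
  if (rad < 1) rad = 1;
  std::vector<double> kern(2 * rad + 1);
  double ksum = 0.0;
  for (int i = -rad; i <= rad; ++i) {
    kern[i + rad] = std::exp(-0.5 * (i * i) / (sigma * sigma));
    ksum += kern[i + rad];
  }
  for (double& w : kern) w /= ksum;
  std::vector<double> buf(n);
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  // pass along x
  double* a = out.begin();
  double* b = buf.data();
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = j * sy + k * sz;
      for (int i = 0; i < nx; ++i) {
        double acc = 0.0;
        for (int d = -rad; d <= rad; ++d) {
          int ii = i + d;
          if (ii < 0) ii = 0; else if (ii >= nx) ii = nx - 1;
          acc += kern[d + rad] * a[base + ii * sx];
        }
        b[base + i * sx] = acc;
      }
    }
  // pass along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i * sx + k * sz;
      for (int j = 0; j < ny; ++j) {
        double acc = 0.0;
        for (int d = -rad; d <= rad; ++d) {
          int jj = j + d;
          if (jj < 0) jj = 0; else if (jj >= ny) jj = ny - 1;
          acc += kern[d + rad] * b[base + jj * sy];
        }
        a[base + j * sy] = acc;
      }
    }
  // pass along z
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i * sx + j * sy;
      for (int k = 0; k < nz; ++k) {
        double acc = 0.0;
        for (int d = -rad; d <= rad; ++d) {
          int kk = k + d;
          if (kk < 0) kk = 0; else if (kk >= nz) kk = nz - 1;
          acc += kern[d + rad] * a[base + kk * sz];
        }
        b[base + k * sz] = acc;
      }
    }
  std::copy(buf.begin(), buf.end(), out.begin());
  return out;
}
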