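#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Sample a 3-D volume at affinely mapped coordinates.
//
// `data` holds the source volume (column-major, dims `sdim`); `M` is a 4x4
// matrix mapping 0-based target voxel indices (i,j,k,1) to 0-based source
// voxel coordinates. Out-of-field samples are 0. mode: 0 = nearest,
// 1 = trilinear.
// [[Rcpp::export(name = ".affine_sample_cpp")]]
NumericVector affine_sample_cpp(NumericVector data, IntegerVector sdim,
                                NumericMatrix M, IntegerVector tdim,
                                int mode) {
  const int nx = sdim[0], ny = sdim[1], nz = sdim[2];
  const int tx = tdim[0], ty = tdim[1], tz = tdim[2];
  const double m00 = M(0, 0), m01 = M(0, 1), m02 = M(0, 2), m03 = M(0, 3);
  const double m10 = M(1, 0), m11 = M(1, 1), m12 = M(1, 2), m13 = M(1, 3);
  const double m20 = M(2, 0), m21 = M(2, 1), m22 = M(2, 2), m23 = M(2, 3);
  const double *src = data.begin();
  NumericVector out((R_xlen_t)tx * ty * tz);
  double *dst = out.begin();

  R_xlen_t idx = 0;
  for (int k = 0; k < tz; ++k) {
    for (int j = 0; j < ty; ++j) {
      // precompute the j,k part of the mapping
      const double bx = m01 * j + m02 * k + m03;
      const double by = m11 * j + m12 * k + m13;
      const double bz = m21 * j + m22 * k + m23;
      for (int i = 0; i < tx; ++i, ++idx) {
        const double x = m00 * i + bx;
        const double y = m10 * i + by;
        const double z = m20 * i + bz;
        if (mode == 0) {
          const int xi = (int)std::lround(x);
          const int yi = (int)std::lround(y);
          const int zi = (int)std::lround(z);
          if (xi < 0 || yi < 0 || zi < 0 || xi >= nx || yi >= ny || zi >= nz)
            dst[idx] = 0.0;
          else
            dst[idx] = src[(R_xlen_t)xi + nx * ((R_xlen_t)yi + (R_xlen_t)ny * zi)];
        } else {
          const int x0 = (int)std::floor(x);
          const int y0 = (int)std::floor(y);
          const int z0 = (int)std::floor(z);
          if (x0 < -1 || y0 < -1 || z0 < -1 ||
              x0 >= nx || y0 >= ny || z0 >= nz) {
            dst[idx] = 0.0;
            continue;
          }
          const double fx = x - x0, fy = y - y0, fz = z - z0;
          double acc = 0.0;
          for (int dz = 0; dz <= 1; ++dz) {
            const int zz = z0 + dz;
            if (zz < 0 || zz >= nz) continue;
            const double wz = dz ? fz : 1.0 - fz;
            for (int dy = 0; dy <= 1; ++dy) {
              const int yy = y0 + dy;
              if (yy < 0 || yy >= ny) continue;
              const double wy = dy ? fy : 1.0 - fy;
              for (int dx = 0; dx <= 1; ++dx) {
                const int xx = x0 + dx;
                if (xx < 0 || xx >= nx) continue;
                const double wx = dx ? fx : 1.0 - fx;
                acc += wx * wy * wz *
                       src[(R_xlen_t)xx + nx * ((R_xlen_t)yy + (R_xlen_t)ny * zz)];
              }
            }
          }
          dst[idx] = acc;
        }
      }
    }
  }
  return out;
}

// Separable 1-D convolution of a 3-D volume along one axis with zero-padded
// borders. axis: 0, 1 or 2. Kernel is applied centred (odd length).
// [[Rcpp::export(name = ".convolve_axis_cpp")]]
NumericVector convolve_axis_cpp(NumericVector data, IntegerVector dim,
                                NumericVector kernel, int axis) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int kl = kernel.size();
  const int r = (kl - 1) / 2;
  const double *src = data.begin();
  const double *w = kernel.begin();
  NumericVector out((R_xlen_t)nx * ny * nz);
  double *dst = out.begin();
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  const R_xlen_t stride = (axis == 0) ? sx : (axis == 1) ? sy : sz;
  const int n = (axis == 0) ? nx : (axis == 1) ? ny : nz;

  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        const R_xlen_t idx = i + sy * j + sz * k;
        const int pos = (axis == 0) ? i : (axis == 1) ? j : k;
        double acc = 0.0;
        const int lo = std::max(-r, -pos);
        const int hi = std::min(r, n - 1 - pos);
        for (int t = lo; t <= hi; ++t)
          acc += w[t + r] * src[idx + t * stride];
        dst[idx] = acc;
      }
    }
  }
  return out;
}
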