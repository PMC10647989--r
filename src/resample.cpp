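#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Catmull-Rom cubic kernel weights for fractional position t in [0,1].
static inline void cr_weights(double t, double w[4]) {
  double t2 = t * t, t3 = t2 * t;
  w[0] = 0.5 * (-t3 + 2 * t2 - t);
  w[1] = 0.5 * (3 * t3 - 5 * t2 + 2);
  w[2] = 0.5 * (-3 * t3 + 4 * t2 + t);
  w[3] = 0.5 * (t3 - t2);
}

static inline int clampi(int x, int lo, int hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// Tricubic (Catmull-Rom) sample with index clamping at the borders;
// positions outside the voxel-center hull return `fill`.
static double tricubic(const NumericVector& v, const IntegerVector& dim,
                       double fx, double fy, double fz, double fill) {
  if (fx < 0 || fy < 0 || fz < 0 ||
      fx > dim[0] - 1 || fy > dim[1] - 1 || fz > dim[2] - 1)
    return fill;
  int i0 = (int)std::floor(fx), j0 = (int)std::floor(fy),
      k0 = (int)std::floor(fz);
  double wx[4], wy[4], wz[4];
  cr_weights(fx - i0, wx);
  cr_weights(fy - j0, wy);
  cr_weights(fz - k0, wz);
  const int nx = dim[0], nxy = dim[0] * dim[1];
  double acc = 0.0;
  for (int dk = -1; dk <= 2; ++dk) {
    int k = clampi(k0 + dk, 0, dim[2] - 1);
    for (int dj = -1; dj <= 2; ++dj) {
      int j = clampi(j0 + dj, 0, dim[1] - 1);
      double wjk = wy[dj + 1] * wz[dk + 1];
      for (int di = -1; di <= 2; ++di) {
        int i = clampi(i0 + di, 0, dim[0] - 1);
        acc += wx[di + 1] * wjk * v[i + nx * j + nxy * k];
      }
    }
  }
  return acc;
}

// Resample a field under the affine source map q = A p + b: the output
// voxel at physical position p takes the tricubic-interpolated value of
// the input field at q. Used for rigid shifts (A = I, b = -shift) and
// rotations about a fixed point.
// [[Rcpp::export(name = ".resample_affine")]]
NumericVector resample_affine(NumericVector v, IntegerVector dim,
                              NumericVector spacing, NumericVector origin,
                              NumericMatrix A, NumericVector b,
                              double fill) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  R_xlen_t idx = 0;
  for (int k = 0; k < nz; ++k) {
    double pz = origin[2] + k * spacing[2];
    for (int j = 0; j < ny; ++j) {
      double py = origin[1] + j * spacing[1];
      for (int i = 0; i < nx; ++i, ++idx) {
        double px = origin[0] + i * spacing[0];
        double qx = A(0, 0) * px + A(0, 1) * py + A(0, 2) * pz + b[0];
        double qy = A(1, 0) * px + A(1, 1) * py + A(1, 2) * pz + b[1];
        double qz = A(2, 0) * px + A(2, 1) * py + A(2, 2) * pz + b[2];
        double fx = (qx - origin[0]) / spacing[0];
        double fy = (qy - origin[1]) / spacing[1];
        double fz = (qz - origin[2]) / spacing[2];
        double val = tricubic(v, dim, fx, fy, fz, fill);
        out[idx] = val < 0 ? 0 : val;  // dose cannot be negative
      }
    }
  }
  return out;
}
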