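#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Trilinear interpolation of a 3D field at a physical position.
// Returns NA when the position falls outside the voxel-center hull.
static inline double interp3(const NumericVector& v, const IntegerVector& dim,
                             const NumericVector& spacing,
                             const NumericVector& origin,
                             double x, double y, double z) {
  double fx = (x - origin[0]) / spacing[0];
  double fy = (y - origin[1]) / spacing[1];
  double fz = (z - origin[2]) / spacing[2];
  if (fx < 0 || fy < 0 || fz < 0 ||
      fx > dim[0] - 1 || fy > dim[1] - 1 || fz > dim[2] - 1)
    return NA_REAL;
  int i0 = (int)std::floor(fx), j0 = (int)std::floor(fy),
      k0 = (int)std::floor(fz);
  if (i0 == dim[0] - 1) i0--;
  if (j0 == dim[1] - 1) j0--;
  if (k0 == dim[2] - 1) k0--;
  if (i0 < 0) i0 = 0;
  if (j0 < 0) j0 = 0;
  if (k0 < 0) k0 = 0;
  double tx = fx - i0, ty = fy - j0, tz = fz - k0;
  const int nx = dim[0], nxy = dim[0] * dim[1];
  double acc = 0.0;
  for (int dk = 0; dk < 2; ++dk)
    for (int dj = 0; dj < 2; ++dj)
      for (int di = 0; di < 2; ++di) {
        double w = (di ? tx : 1 - tx) * (dj ? ty : 1 - ty) *
                   (dk ? tz : 1 - tz);
        acc += w * v[(i0 + di) + nx * (j0 + dj) + nxy * (k0 + dk)];
      }
  return acc;
}

// Global gamma index with sorted-offset search and early termination.
// offsets: m x 3 matrix of displacement vectors (mm), sorted by norm
// ascending, first row (0,0,0). Returns per-reference-voxel gamma
// (NA below cutoff or where no evaluated sample was reachable).
// [[Rcpp::export(name = ".gamma_engine")]]
NumericVector gamma_engine(NumericVector ref, IntegerVector ref_dim,
                           NumericVector ref_spacing, NumericVector ref_origin,
                           NumericVector ev, IntegerVector ev_dim,
                           NumericVector ev_spacing, NumericVector ev_origin,
                           NumericMatrix offsets, NumericVector offset_norm,
                           double dose_tol, double dta, double cutoff_dose) {
  const int n = ref.size();
  const int m = offsets.nrow();
  NumericVector out(n, NA_REAL);
  const int nx = ref_dim[0], ny = ref_dim[1];
  const double dta2 = dta * dta;

  for (int idx = 0; idx < n; ++idx) {
    double dref = ref[idx];
    if (dref < cutoff_dose) continue;
    int i = idx % nx;
    int j = (idx / nx) % ny;
    int k = idx / (nx * ny);
    double px = ref_origin[0] + i * ref_spacing[0];
    double py = ref_origin[1] + j * ref_spacing[1];
    double pz = ref_origin[2] + k * ref_spacing[2];

    double best = R_PosInf;  // squared gamma
    for (int s = 0; s < m; ++s) {
      double dist2 = offset_norm[s] * offset_norm[s] / dta2;
      if (dist2 >= best) break;  // offsets sorted: no improvement possible
      double de = interp3(ev, ev_dim, ev_spacing, ev_origin,
                          px + offsets(s, 0), py + offsets(s, 1),
                          pz + offsets(s, 2));
      if (ISNA(de)) continue;
      double dd = (de - dref) / dose_tol;
      double cand = dd * dd + dist2;
      if (cand < best) best = cand;
    }
    if (R_finite(best)) out[idx] = std::sqrt(best);
  }
  return out;
}
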