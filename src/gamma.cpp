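#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Trilinear interpolation of a grid sampled at voxel centers; coordinates in
// voxel-index units (0 .. n-1). Returns NA outside the grid support.
static inline double interp3(const double *a, int nx, int ny, int nz,
                             double x, double y, double z) {
  if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1)
    return NA_REAL;
  int i0 = std::min(int(x), nx - 2 >= 0 ? nx - 2 : 0);
  int j0 = std::min(int(y), ny - 2 >= 0 ? ny - 2 : 0);
  int k0 = std::min(int(z), nz - 2 >= 0 ? nz - 2 : 0);
  if (nx == 1) i0 = 0;
  if (ny == 1) j0 = 0;
  if (nz == 1) k0 = 0;
  double fx = nx == 1 ? 0 : x - i0, fy = ny == 1 ? 0 : y - j0,
         fz = nz == 1 ? 0 : z - k0;
  int i1 = nx == 1 ? 0 : i0 + 1, j1 = ny == 1 ? 0 : j0 + 1,
      k1 = nz == 1 ? 0 : k0 + 1;
#define AT(i, j, k) a[(i) + nx * ((j) + ny * (k))]
  double c00 = AT(i0, j0, k0) * (1 - fx) + AT(i1, j0, k0) * fx;
  double c10 = AT(i0, j1, k0) * (1 - fx) + AT(i1, j1, k0) * fx;
  double c01 = AT(i0, j0, k1) * (1 - fx) + AT(i1, j0, k1) * fx;
  double c11 = AT(i0, j1, k1) * (1 - fx) + AT(i1, j1, k1) * fx;
#undef AT
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// Gamma index with exhaustive search over a subsampled neighborhood.
// vox: voxel sizes (cm); dcrit in dose units; dta in cm; offsets are laid on
// a cubic subgrid of step `sub` cm within radius cap*dta, visited in order
// of increasing distance with early termination on the distance term.
// [[Rcpp::export]]
NumericVector gamma_index_cpp(NumericVector ref, NumericVector eval,
                              IntegerVector dims, NumericVector vox,
                              double dcrit, double dta, double roi_abs,
                              double cap, double sub) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  double rmax = cap * dta;
  int mx = nx > 1 ? int(rmax / sub) : 0;
  int my = ny > 1 ? int(rmax / sub) : 0;
  int mz = nz > 1 ? int(rmax / sub) : 0;

  struct Off { double ox, oy, oz, r2; };
  std::vector<Off> offs;
  for (int a = -mx; a <= mx; ++a)
    for (int b = -my; b <= my; ++b)
      for (int c = -mz; c <= mz; ++c) {
        double ox = a * sub, oy = b * sub, oz = c * sub;
        double r2 = ox * ox + oy * oy + oz * oz;
        if (r2 <= rmax * rmax) offs.push_back({ox, oy, oz, r2});
      }
  std::sort(offs.begin(), offs.end(),
            [](const Off &u, const Off &v) { return u.r2 < v.r2; });

  NumericVector gamma(n, NA_REAL);
  double dta2 = dta * dta;
  const double *ev = eval.begin();
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int c = i + nx * (j + ny * k);
        double dr = ref[c];
        if (dr <= roi_abs) continue;
        double best = R_PosInf;
        for (size_t o = 0; o < offs.size(); ++o) {
          double dterm = offs[o].r2 / dta2;
          if (dterm >= best) break;  // sorted by distance
          double xe = i + offs[o].ox / vox[0];
          double ye = j + offs[o].oy / vox[1];
          double ze = k + offs[o].oz / vox[2];
          double de = interp3(ev, nx, ny, nz, xe, ye, ze);
          if (ISNA(de)) continue;
          double dd = (de - dr) / dcrit;
          double g2 = dd * dd + dterm;
          if (g2 < best) best = g2;
        }
        gamma[c] = std::sqrt(best);
      }
  return gamma;
}
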