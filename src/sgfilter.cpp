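// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Locally adaptive Savitzky-Golay smoother. Per voxel: try window half-widths
// in the given (descending) order; fit an order-2 polynomial by weighted
// least squares (weights 1/sigma^2) and accept the largest window whose
// reduced chi-squared does not exceed 1 + chi_mult*sqrt(2/nu). The fitted
// central value replaces the voxel; its uncertainty comes from the fit
// covariance. Voxels where no window passes (or with no usable sigma) are
// returned unsmoothed.
// [[Rcpp::export]]
List sg_filter_cpp(NumericVector dose, NumericVector sigma,
                   IntegerVector dims, IntegerVector halfwidths,
                   double chi_mult) {
  int nx = dims[0], ny = dims[1], nzd = dims[2];
  int n = nx * ny * nzd;
  NumericVector val(n), sd(n);
  IntegerVector win(n);

  // full quadratic basis exponents in 3D
  const int P = 10;
  int ex[P] = {0, 1, 0, 0, 2, 0, 0, 1, 1, 0};
  int ey[P] = {0, 0, 1, 0, 0, 2, 0, 1, 0, 1};
  int ez[P] = {0, 0, 0, 1, 0, 0, 2, 0, 1, 1};

  arma::mat A(P, P);
  arma::vec b(P), beta(P), e0(P);
  arma::vec basis(P);

  for (int k = 0; k < nzd; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int c = i + nx * (j + ny * k);
        double d0 = dose[c], s0 = sigma[c];
        val[c] = d0; sd[c] = s0; win[c] = 0;
        if (!(s0 > 0)) continue;
        for (int hw = 0; hw < halfwidths.size(); ++hw) {
          int h = halfwidths[hw];
          int ia = std::max(i - h, 0), ib = std::min(i + h, nx - 1);
          int ja = std::max(j - h, 0), jb = std::min(j + h, ny - 1);
          int ka = std::max(k - h, 0), kb = std::min(k + h, nzd - 1);
          // active polynomial terms: drop axes with no extent
          bool actx = ib > ia, acty = jb > ja, actz = kb > ka;
          std::vector<int> terms;
          for (int p = 0; p < P; ++p) {
            if ((ex[p] > 0 && !actx) || (ey[p] > 0 && !acty) ||
                (ez[p] > 0 && !actz)) continue;
            terms.push_back(p);
          }
          int Pa = terms.size();
          A.zeros(Pa, Pa); b.zeros(Pa);
          int npts = 0;
          for (int kk = ka; kk <= kb; ++kk)
            for (int jj = ja; jj <= jb; ++jj)
              for (int ii = ia; ii <= ib; ++ii) {
                int cc = ii + nx * (jj + ny * kk);
                double s = sigma[cc];
                if (!(s > 0)) continue;
                double w = 1.0 / (s * s);
                double dxo = ii - i, dyo = jj - j, dzo = kk - k;
                for (int p = 0; p < Pa; ++p) {
                  int t = terms[p];
                  double v = 1.0;
                  for (int q = 0; q < ex[t]; ++q) v *= dxo;
                  for (int q = 0; q < ey[t]; ++q) v *= dyo;
                  for (int q = 0; q < ez[t]; ++q) v *= dzo;
                  basis[p] = v;
                }
                ++npts;
                for (int p = 0; p < Pa; ++p) {
                  b[p] += w * basis[p] * dose[cc];
                  for (int q = p; q < Pa; ++q)
                    A(p, q) += w * basis[p] * basis[q];
                }
              }
          int nu = npts - Pa;
          if (nu < 1) continue;
          for (int p = 0; p < Pa; ++p)
            for (int q = 0; q < p; ++q) A(p, q) = A(q, p);
          arma::mat Asub = A.submat(0, 0, Pa - 1, Pa - 1);
          arma::vec bsub = b.subvec(0, Pa - 1);
          arma::vec bet;
          bool oks = arma::solve(bet, Asub, bsub,
                                 arma::solve_opts::no_approx);
          if (!oks) continue;
          // chi-squared of the fit over the window
          double chi2 = 0.0;
          for (int kk = ka; kk <= kb; ++kk)
            for (int jj = ja; jj <= jb; ++jj)
              for (int ii = ia; ii <= ib; ++ii) {
                int cc = ii + nx * (jj + ny * kk);
                double s = sigma[cc];
                if (!(s > 0)) continue;
                double dxo = ii - i, dyo = jj - j, dzo = kk - k;
                double fit = 0.0;
                for (int p = 0; p < Pa; ++p) {
                  int t = terms[p];
                  double v = 1.0;
                  for (int q = 0; q < ex[t]; ++q) v *= dxo;
                  for (int q = 0; q < ey[t]; ++q) v *= dyo;
                  for (int q = 0; q < ez[t]; ++q) v *= dzo;
                  fit += bet[p] * v;
                }
                double r = (dose[cc] - fit) / s;
                chi2 += r * r;
              }
          double chired = chi2 / nu;
          if (chired <= 1.0 + chi_mult * std::sqrt(2.0 / nu)) {
            arma::vec ee(Pa, arma::fill::zeros);
            ee[0] = 1.0;
            arma::vec cov0;
            if (arma::solve(cov0, Asub, ee, arma::solve_opts::no_approx)) {
              val[c] = bet[0];
              sd[c] = std::sqrt(std::max(cov0[0], 0.0));
              win[c] = h;
            }
            break;
          }
        }
      }
  return List::create(_["value"] = val, _["sd"] = sd, _["window"] = win);
}
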