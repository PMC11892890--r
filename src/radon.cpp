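// Parallel-beam geometry for square slices: forward projection (discrete
// line integrals) and back projection with linear detector interpolation.
//
// Conventions: centered coordinates x = col - (n-1)/2, y = row - (n-1)/2;
// a point (x0, y0) projects to detector coordinate d = x0*cos(t) + y0*sin(t);
// samples outside the grid contribute zero.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// [[Rcpp::export]]
arma::mat radon_slice_cpp(const arma::mat& img, const arma::vec& angles) {
  const int n = img.n_rows;
  const int n_a = angles.n_elem;
  const double c = (n - 1) / 2.0;
  mat out(n_a, n, fill::zeros);
  for (int a = 0; a < n_a; ++a) {
    const double ct = std::cos(angles[a]);
    const double st = std::sin(angles[a]);
    for (int d = 0; d < n; ++d) {
      const double dd = d - c;
      double sum = 0.0;
      for (int k = 0; k < n; ++k) {
        const double kk = k - c;
        const double col = dd * ct - kk * st + c;
        const double row = dd * st + kk * ct + c;
        const int r0 = (int)std::floor(row);
        const int c0 = (int)std::floor(col);
        if (r0 < -1 || r0 > n - 1 || c0 < -1 || c0 > n - 1) continue;
        const double fr = row - r0, fc = col - c0;
        double v = 0.0;
        if (r0 >= 0 && c0 >= 0)             v += (1 - fr) * (1 - fc) * img(r0, c0);
        if (r0 >= 0 && c0 + 1 <= n - 1)     v += (1 - fr) * fc * img(r0, c0 + 1);
        if (r0 + 1 <= n - 1 && c0 >= 0)     v += fr * (1 - fc) * img(r0 + 1, c0);
        if (r0 + 1 <= n - 1 && c0 + 1 <= n - 1) v += fr * fc * img(r0 + 1, c0 + 1);
        sum += v;
      }
      out(a, d) = sum;
    }
  }
  return out;
}

// Back projection of one (already filtered) sinogram, scaled by pi/(2*N_a).
// [[Rcpp::export]]
arma::mat backproject_slice_cpp(const arma::mat& fsino, const arma::vec& angles) {
  const int n_a = fsino.n_rows;
  const int n = fsino.n_cols;
  const double c = (n - 1) / 2.0;
  mat out(n, n, fill::zeros);
  for (int a = 0; a < n_a; ++a) {
    const double ct = std::cos(angles[a]);
    const double st = std::sin(angles[a]);
    for (int xi = 0; xi < n; ++xi) {
      const double xc = (xi - c) * ct + c;
      for (int yi = 0; yi < n; ++yi) {
        const double dd = xc + (yi - c) * st;
        const int i0 = (int)std::floor(dd);
        const double f = dd - i0;
        double v = 0.0;
        if (i0 >= 0 && i0 <= n - 1) v += (1 - f) * fsino(a, i0);
        if (i0 + 1 >= 0 && i0 + 1 <= n - 1) v += f * fsino(a, i0 + 1);
        out(yi, xi) += v;
      }
    }
  }
  return out * (datum::pi / (2.0 * n_a));
}
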