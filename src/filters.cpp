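// Small image filters: 2D median (reflected edges) and separable
// valid-mode convolution used by the SSIM window.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline int refl(int i, int n) {
  if (n <= 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i; else i = 2 * n - 2 - i;
  }
  return i;
}

// [[Rcpp::export]]
arma::mat median_filter_cpp(const arma::mat& x, int size) {
  const int H = x.n_rows, W = x.n_cols, h = size / 2;
  mat out(H, W);
  std::vector<double> win((size_t)size * size);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      size_t m = 0;
      for (int dj = -h; dj <= h; ++dj)
        for (int di = -h; di <= h; ++di)
          win[m++] = x(refl(i + di, H), refl(j + dj, W));
      std::nth_element(win.begin(), win.begin() + m / 2, win.begin() + m);
      double med = win[m / 2];
      if (m % 2 == 0) {
        std::nth_element(win.begin(), win.begin() + m / 2 - 1, win.begin() + m / 2);
        med = 0.5 * (med + win[m / 2 - 1]);
      }
      out(i, j) = med;
    }
  }
  return out;
}

// Separable valid-mode correlation with a symmetric 1D kernel.
// [[Rcpp::export]]
arma::mat sep_filter_valid_cpp(const arma::mat& x, const arma::vec& k) {
  const int L = k.n_elem;
  const int H = x.n_rows, W = x.n_cols;
  mat tmp(H - L + 1, W, fill::zeros);
  for (int t = 0; t < L; ++t)
    tmp += k[t] * x.rows(t, t + H - L);
  mat out(H - L + 1, W - L + 1, fill::zeros);
  for (int t = 0; t < L; ++t)
    out += k[t] * tmp.cols(t, t + W - L);
  return out;
}
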