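// Foam-phantom construction: rejection sampling of non-overlapping bubbles
// inside a cylinder (cell-list accelerated) and voxelization.
//
// Physical coordinates: index i maps to i - (size-1)/2; cylinder axis along Z.
// Uses the R RNG so results are reproducible from set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// [[Rcpp::export]]
Rcpp::List place_bubbles_cpp(int n_bubbles, double size, double r_cyl,
                             double r_min, double r_max,
                             int max_attempts_per_bubble) {
  const double half = (size - 1) / 2.0;
  std::vector<double> bx, by, bz, br;
  bx.reserve(n_bubbles); by.reserve(n_bubbles);
  bz.reserve(n_bubbles); br.reserve(n_bubbles);

  // cell list over the bounding cube, cell edge = bubble diameter upper bound
  const double cell = std::max(2.0 * r_max, 1.0);
  const int nc = std::max(1, (int)std::ceil(size / cell));
  std::vector<std::vector<int>> cells((size_t)nc * nc * nc);
  auto cell_of = [&](double v) {
    int i = (int)std::floor((v + half) / cell);
    return std::min(std::max(i, 0), nc - 1);
  };

  const double lr_min = std::log(r_min), lr_max = std::log(r_max);
  long long budget = (long long)max_attempts_per_bubble * std::max(n_bubbles, 1);
  long long attempts = 0;

  for (int b = 0; b < n_bubbles; ++b) {
    bool placed = false;
    while (!placed) {
      if (++attempts > budget)
        Rcpp::stop("failed to place bubble %d of %d within %lld attempts",
                   b + 1, n_bubbles, budget);
      const double r = std::exp(R::runif(lr_min, lr_max));
      const double rad_max = r_cyl - r;
      if (rad_max <= 0) continue;
      // uniform in the admissible disk via rejection from the square
      double x, y;
      do {
        x = R::runif(-rad_max, rad_max);
        y = R::runif(-rad_max, rad_max);
      } while (x * x + y * y > rad_max * rad_max);
      const double z = R::runif(-half + r, half - r);

      const int reach = (int)std::ceil((r + r_max) / cell);
      const int cx = cell_of(x), cy = cell_of(y), cz = cell_of(z);
      bool ok = true;
      for (int ix = std::max(0, cx - reach); ok && ix <= std::min(nc - 1, cx + reach); ++ix)
        for (int iy = std::max(0, cy - reach); ok && iy <= std::min(nc - 1, cy + reach); ++iy)
          for (int iz = std::max(0, cz - reach); ok && iz <= std::min(nc - 1, cz + reach); ++iz)
            for (int q : cells[(size_t)ix + nc * ((size_t)iy + nc * iz)]) {
              const double dx = x - bx[q], dy = y - by[q], dz = z - bz[q];
              const double rr = r + br[q];
              if (dx * dx + dy * dy + dz * dz <= rr * rr) { ok = false; break; }
            }
      if (!ok) continue;
      bx.push_back(x); by.push_back(y); bz.push_back(z); br.push_back(r);
      cells[(size_t)cx + nc * ((size_t)cy + nc * cz)].push_back(b);
      placed = true;
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("x") = bx, Rcpp::Named("y") = by,
      Rcpp::Named("z") = bz, Rcpp::Named("r") = br);
}

// Voxelize: value mu inside the cylinder, 0 outside and inside bubbles.
// Output is an R array with dim (Z, Y, X).
// [[Rcpp::export]]
Rcpp::NumericVector voxelize_foam_cpp(int size, double r_cyl, double mu,
                                      const arma::vec& bx, const arma::vec& by,
                                      const arma::vec& bz, const arma::vec& br) {
  const double half = (size - 1) / 2.0;
  Rcpp::NumericVector out((R_xlen_t)size * size * size);
  double* o = out.begin();
  const double r2 = r_cyl * r_cyl;
  // index (z, y, x) -> z + size*(y + size*x)
  for (int x = 0; x < size; ++x) {
    const double xc = x - half;
    for (int y = 0; y < size; ++y) {
      const double yc = y - half;
      if (xc * xc + yc * yc <= r2) {
        double* col = o + (R_xlen_t)size * (y + (R_xlen_t)size * x);
        for (int z = 0; z < size; ++z) col[z] = mu;
      }
    }
  }
  for (uword b = 0; b < br.n_elem; ++b) {
    const double cx = bx[b] + half, cy = by[b] + half, cz = bz[b] + half;
    const double r = br[b], rr = r * r;
    const int x0 = std::max(0, (int)std::floor(cx - r)), x1 = std::min(size - 1, (int)std::ceil(cx + r));
    const int y0 = std::max(0, (int)std::floor(cy - r)), y1 = std::min(size - 1, (int)std::ceil(cy + r));
    const int z0 = std::max(0, (int)std::floor(cz - r)), z1 = std::min(size - 1, (int)std::ceil(cz + r));
    for (int x = x0; x <= x1; ++x) {
      const double dx = x - cx;
      for (int y = y0; y <= y1; ++y) {
        const double dy = y - cy;
        const double d2 = dx * dx + dy * dy;
        if (d2 > rr) continue;
        double* col = o + (R_xlen_t)size * (y + (R_xlen_t)size * x);
        for (int z = z0; z <= z1; ++z) {
          const double dz = z - cz;
          if (d2 + dz * dz < rr) col[z] = 0.0;
        }
      }
    }
  }
  out.attr("dim") = Rcpp::IntegerVector::create(size, size, size);
  return out;
}
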