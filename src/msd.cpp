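// Mixed-scale dense network: forward pass and exact backpropagation.
//
// Parameter packing (one flat numeric vector, in this order):
//   for each dense layer i = 1..depth (c_prev = c_in + i - 1 input channels):
//     9 * c_prev convolution weights (channel-major; within a channel the
//     3x3 taps are stored column-major over (dy, dx) in {-1, 0, 1}^2),
//     then 1 bias;
//   final 1x1 layer: (c_in + depth) * c_out weights (channel-major per
//     output channel), then c_out biases.
//
// Spatial size is preserved through reflection padding (no edge repeat).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline int reflect_idx(int i, int n) {
  if (n <= 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i; else i = 2 * n - 2 - i;
  }
  return i;
}

static mat pad_reflect(const mat& x, int p) {
  const int H = x.n_rows, W = x.n_cols;
  mat out(H + 2 * p, W + 2 * p);
  std::vector<int> ry(H + 2 * p), rx(W + 2 * p);
  for (int i = 0; i < H + 2 * p; ++i) ry[i] = reflect_idx(i - p, H);
  for (int j = 0; j < W + 2 * p; ++j) rx[j] = reflect_idx(j - p, W);
  for (int j = 0; j < W + 2 * p; ++j)
    for (int i = 0; i < H + 2 * p; ++i)
      out(i, j) = x(ry[i], rx[j]);
  return out;
}

// Adjoint of pad_reflect: fold padded borders back onto their source pixels.
static mat pad_reflect_adj(const mat& P, int p, int H, int W) {
  mat out = P.submat(p, p, p + H - 1, p + W - 1);
  const int Hp = H + 2 * p, Wp = W + 2 * p;
  for (int j = 0; j < Wp; ++j) {
    const int sx = reflect_idx(j - p, W);
    const bool x_interior = (j >= p && j < p + W);
    for (int i = 0; i < Hp; ++i) {
      if (x_interior && i >= p && i < p + H) continue;
      out(reflect_idx(i - p, H), sx) += P(i, j);
    }
  }
  return out;
}

// Dense-layer forward shared by inference and training paths.  Activations
// for all channels (inputs + every layer output) are kept in one cube.
static void msd_dense_forward(const vec& params, cube& C, int c_in, int depth,
                              const ivec& dilations, int H, int W,
                              std::vector<int>& layer_off) {
  int off = 0;
  for (int i = 0; i < depth; ++i) {
    layer_off[i] = off;
    const int c_prev = c_in + i;
    const int dil = dilations[i];
    mat z(H, W, fill::zeros);
    for (int j = 0; j < c_prev; ++j) {
      mat P = pad_reflect(C.slice(j), dil);
      const double* w = params.memptr() + off + 9 * j;
      int t = 0;
      for (int dx = -1; dx <= 1; ++dx) {
        for (int dy = -1; dy <= 1; ++dy) {
          const double wt = w[t++];
          if (wt != 0.0) {
            const int r0 = dil + dy * dil, c0 = dil + dx * dil;
            z += wt * P.submat(r0, c0, r0 + H - 1, c0 + W - 1);
          }
        }
      }
    }
    off += 9 * c_prev;
    z += params[off];
    off += 1;
    C.slice(c_in + i) = clamp(z, 0.0, datum::inf);  // ReLU
  }
  layer_off[depth] = off;  // start of the final 1x1 layer
}

// [[Rcpp::export]]
arma::cube msd_forward_cpp(const arma::vec& params, const arma::cube& input,
                           int depth, int c_out, const arma::ivec& dilations) {
  const int H = input.n_rows, W = input.n_cols, c_in = input.n_slices;
  const int c_tot = c_in + depth;
  cube C(H, W, c_tot);
  for (int c = 0; c < c_in; ++c) C.slice(c) = input.slice(c);
  std::vector<int> layer_off(depth + 1);
  msd_dense_forward(params, C, c_in, depth, dilations, H, W, layer_off);
  const int off = layer_off[depth];
  cube out(H, W, c_out, fill::zeros);
  for (int o = 0; o < c_out; ++o) {
    for (int c = 0; c < c_tot; ++c)
      out.slice(o) += params[off + o * c_tot + c] * C.slice(c);
    out.slice(o) += params[off + c_out * c_tot + o];
  }
  return out;
}

// Mean-squared-error loss and its gradient with respect to every parameter,
// for a single (input, target) pair with c_out = 1.
// [[Rcpp::export]]
Rcpp::List msd_loss_grad_cpp(const arma::vec& params, const arma::cube& input,
                             const arma::mat& target, int depth,
                             const arma::ivec& dilations) {
  const int H = input.n_rows, W = input.n_cols, c_in = input.n_slices;
  const int c_tot = c_in + depth;
  cube C(H, W, c_tot);
  for (int c = 0; c < c_in; ++c) C.slice(c) = input.slice(c);
  std::vector<int> layer_off(depth + 1);
  msd_dense_forward(params, C, c_in, depth, dilations, H, W, layer_off);
  const int off_f = layer_off[depth];

  mat out(H, W, fill::zeros);
  for (int c = 0; c < c_tot; ++c) out += params[off_f + c] * C.slice(c);
  out += params[off_f + c_tot];

  const mat resid = out - target;
  const double loss = accu(square(resid)) / resid.n_elem;
  const mat g = (2.0 / resid.n_elem) * resid;

  vec grad(params.n_elem, fill::zeros);
  cube dC(H, W, c_tot, fill::zeros);
  for (int c = 0; c < c_tot; ++c) {
    grad[off_f + c] = accu(g % C.slice(c));
    dC.slice(c) += params[off_f + c] * g;
  }
  grad[off_f + c_tot] = accu(g);

  for (int i = depth - 1; i >= 0; --i) {
    const int c_prev = c_in + i;
    const int dil = dilations[i];
    const int off = layer_off[i];
    const int li = c_in + i;
    // ReLU derivative: the stored activation is positive iff the unit fired
    mat delta = dC.slice(li) % conv_to<mat>::from(C.slice(li) > 0);
    grad[off + 9 * c_prev] += accu(delta);
    for (int j = 0; j < c_prev; ++j) {
      mat P = pad_reflect(C.slice(j), dil);
      mat Q(H + 2 * dil, W + 2 * dil, fill::zeros);
      const double* w = params.memptr() + off + 9 * j;
      double* gw = grad.memptr() + off + 9 * j;
      int t = 0;
      for (int dx = -1; dx <= 1; ++dx) {
        for (int dy = -1; dy <= 1; ++dy) {
          const int r0 = dil + dy * dil, c0 = dil + dx * dil;
          gw[t] += accu(P.submat(r0, c0, r0 + H - 1, c0 + W - 1) % delta);
          if (w[t] != 0.0)
            Q.submat(r0, c0, r0 + H - 1, c0 + W - 1) += w[t] * delta;
          ++t;
        }
      }
      dC.slice(j) += pad_reflect_adj(Q, dil, H, W);
    }
  }

  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grad") = grad);
}
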