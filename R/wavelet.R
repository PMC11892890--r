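# Orthogonal multilevel 2D discrete wavelet transform with periodization,
# used by the wavelet-Fourier ring filter.  Analysis:
#   a[k] = sum_t h[t] x[(2k + t) mod n],  d[k] = sum_t g[t] x[(2k + t) mod n]
# with the quadrature-mirror highpass g[t] = (-1)^t h[L - 1 - t].  For an
# orthonormal filter bank the transform matrix is orthogonal, so synthesis
# is its transpose and reconstruction is exact for even n.

wavelet_filters <- function(wname) {
  h <- switch(wname,
    haar = c(0.70710678118654757, 0.70710678118654757),
    db2 = c(-0.12940952255126037, 0.22414386804201339,
            0.83651630373780794, 0.48296291314453416),
    sym5 = c(0.027333068345077982, 0.029519490925774643,
             -0.039134249302383094, 0.1993975339773936,
             0.72340769040242059, 0.63397896345821192,
             0.016602105764522319, -0.17532808990845047,
             -0.021101834024758855, 0.019538882735286728),
    stopf("unknown wavelet '%s' (available: haar, db2, sym5)", wname))
  L <- length(h)
  g <- (-1)^(0:(L - 1)) * rev(h)
  list(h = h, g = g)
}

# One analysis step along the columns of x (length must be even).
dwt_cols <- function(x, flt) {
  n <- nrow(x)
  half <- n / 2
  a <- matrix(0, half, ncol(x))
  d <- a
  for (t in seq_along(flt$h)) {
    idx <- (2 * (seq_len(half) - 1) + t - 1) %% n + 1
    xs <- x[idx, , drop = FALSE]
    a <- a + flt$h[t] * xs
    d <- d + flt$g[t] * xs
  }
  list(a = a, d = d)
}

idwt_cols <- function(a, d, flt) {
  half <- nrow(a)
  n <- 2 * half
  x <- matrix(0, n, ncol(a))
  for (t in seq_along(flt$h)) {
    idx <- (2 * (seq_len(half) - 1) + t - 1) %% n + 1
    x[idx, ] <- x[idx, ] + flt$h[t] * a + flt$g[t] * d
  }
  x
}

# One 2D analysis step: first along rows (axis 1), then along columns
# (axis 2).  Returns the four subbands; `ad` is lowpass along axis 1 and
# highpass along axis 2.
dwt2_step <- function(x, flt) {
  s1 <- dwt_cols(x, flt)
  sa <- dwt_cols(t(s1$a), flt)
  sd <- dwt_cols(t(s1$d), flt)
  list(aa = t(sa$a), ad = t(sa$d), da = t(sd$a), dd = t(sd$d))
}

idwt2_step <- function(b, flt) {
  a1 <- t(idwt_cols(t(b$aa), t(b$ad), flt))
  d1 <- t(idwt_cols(t(b$da), t(b$dd), flt))
  idwt_cols(a1, d1, flt)
}
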