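#' Forward project a volume (parallel beam)
#'
#' Slice-wise 2D parallel-beam line integrals of the attenuation volume: the
#' detector has as many columns as the slice width and one row per slice; a
#' point at centered coordinates `(x0, y0)` projects to detector coordinate
#' `x0 * cos(theta) + y0 * sin(theta)`.  Pure rotation and line integration;
#' no noise is added here.
#'
#' @param vol 3D array `(Z, Y, X)` with square slices (`Y == X`).
#' @param angles Angles in radians (see [angle_set()]).
#' @return A [projection_stack()] with dim `(N_a, Z, X)`.
#' @export
forward_project <- function(vol, angles) {
  d <- dim(vol)
  if (length(d) != 3L) stopf("vol must be a 3D array")
  if (d[2] != d[3]) stopf("slices must be square (Y == X), got %d x %d", d[2], d[3])
  check_angles(angles)
  n_a <- length(angles)
  out <- array(0, dim = c(n_a, d[1], d[3]))
  for (z in seq_len(d[1]))
    out[, z, ] <- radon_slice_cpp(vol[z, , ], angles)
  projection_stack(out, angles)
}

#' Rearrange projections into sinograms (and back)
#'
#' A lossless axis permutation: `s[m, a, n] = p[a, m, n]`.  Applying
#' `inverse_rearrange()` after `rearrange()` returns the original stack
#' bitwise.
#'
#' @param p A [projection_stack()].
#' @return A [sinogram_stack()].
#' @export
rearrange <- function(p) {
  if (!inherits(p, "projection_stack")) stopf("p must be a projection_stack")
  sinogram_stack(aperm(p$data, c(2, 1, 3)), p$angles)
}

#' @rdname rearrange
#' @param s A [sinogram_stack()].
#' @export
inverse_rearrange <- function(s) {
  if (!inherits(s, "sinogram_stack")) stopf("s must be a sinogram_stack")
  projection_stack(aperm(s$data, c(2, 1, 3)), s$angles)
}

#' Upsample a sinogram stack along the angle axis
#'
#' Linear interpolation to `factor` times as many equally spaced angles on
#' `[0, pi)`.  Interpolation past the last measured angle is wrap-aware,
#' using the parallel-beam identity `s(theta + pi, n) = s(theta, N - 1 - n)`.
#' `factor = 1` returns an identical copy.
#'
#' @param s A [sinogram_stack()] with equally spaced angles starting at 0.
#' @param factor Integer upsampling factor (>= 1).
#' @return A [sinogram_stack()] with `factor * N_a` angles.
#' @export
angle_upsample <- function(s, factor) {
  if (!inherits(s, "sinogram_stack")) stopf("s must be a sinogram_stack")
  if (!is_count(factor)) stopf("factor must be an integer >= 1")
  factor <- as.integer(factor)
  if (factor == 1L) return(s)
  n_a <- dim(s$data)[2]
  exp_angles <- angle_set(n_a)
  if (max(abs(s$angles - exp_angles)) > 1e-9)
    stopf("angle_upsample requires equally spaced angles starting at 0")
  d <- dim(s$data)
  n_hq <- n_a * factor
  out <- array(0, dim = c(d[1], n_hq, d[3]))
  # wrapped continuation: row at index n_a is the detector-flipped row 0
  wrap <- s$data[, 1L, d[3]:1, drop = FALSE]
  ext <- array(0, dim = c(d[1], n_a + 1L, d[3]))
  ext[, seq_len(n_a), ] <- s$data
  ext[, n_a + 1L, ] <- wrap
  for (r in 0:(factor - 1L)) {
    w <- r / factor
    j <- seq_len(n_a)
    out[, (j - 1L) * factor + r + 1L, ] <-
      (1 - w) * ext[, j, , drop = FALSE] + w * ext[, j + 1L, , drop = FALSE]
  }
  sinogram_stack(out, angle_set(n_hq))
}

# Spatial-domain ramp (Ram-Lak) filter evaluated on a circular grid of n
# samples, returned as its frequency response.
ramp_filter_freq <- function(n) {
  j <- 1:(n - 1)
  m <- pmin(j, n - j)  # circular spatial offset
  f <- c(0.25, ifelse(m %% 2 == 1, -1 / (pi * m)^2, 0))
  2 * Re(stats::fft(f))
}

#' Filtered back projection
#'
#' Slice-by-slice FBP with a ramp (Ram-Lak) filter applied in Fourier space
#' (zero-padded) and linear-interpolation back projection.  The result is
#' scaled by `pi / (2 * N_a)` so that round-trip amplitude is preserved; no
#' circular mask is applied.  The operation is linear in its input.
#'
#' @param s A [sinogram_stack()] with at least 2 angles.
#' @return A 3D array `(M, N, N)`: one reconstructed square slice per
#'   detector row.
#' @export
fbp_reconstruct <- function(s) {
  if (!inherits(s, "sinogram_stack")) stopf("s must be a sinogram_stack")
  d <- dim(s$data)
  if (d[2] < 2L) stopf("FBP needs at least 2 angles, got %d", d[2])
  n <- d[3]
  npad <- max(64L, 2L^ceiling(log2(2L * n)))
  filt <- ramp_filter_freq(npad)
  out <- array(0, dim = c(d[1], n, n))
  for (m in seq_len(d[1])) {
    sino <- s$data[m, , , drop = TRUE]
    if (d[2] == 1L) sino <- matrix(sino, nrow = 1L)
    padded <- matrix(0, npad, d[2])          # columns = angles
    padded[seq_len(n), ] <- t(sino)
    fq <- stats::mvfft(padded) * filt
    filtered <- Re(stats::mvfft(fq, inverse = TRUE)) / npad
    out[m, , ] <- backproject_slice_cpp(t(filtered[seq_len(n), , drop = FALSE]),
                                        s$angles)
  }
  out
}
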