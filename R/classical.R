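#' Median-filter zinger removal
#'
#' Classical projection-domain operator: in each projection image, pixels
#' exceeding their local median (window `size` x `size`, reflected edges)
#' by more than `dif` are replaced by that median.  Detection is one-sided
#' (positive outliers only), matching the detector-saturation mechanism of
#' zingers; all other pixels are untouched.
#'
#' @param p A [projection_stack()].
#' @param dif Outlier threshold above the local median (> 0).
#' @param size Odd median window size (>= 3).
#' @return A [projection_stack()].
#' @export
remove_zinger_median <- function(p, dif = 0.5, size = 3L) {
  if (!inherits(p, "projection_stack")) stopf("p must be a projection_stack")
  if (!is_count(size, min = 3) || size %% 2 == 0)
    stopf("size must be an odd integer >= 3")
  if (!is.numeric(dif) || dif <= 0) stopf("dif must be > 0")
  d <- dim(p$data)
  data <- p$data
  for (a in seq_len(d[1])) {
    img <- data[a, , ]
    med <- median_filter_cpp(img, size)
    out <- ifelse(img - med > dif, med, img)
    data[a, , ] <- out
  }
  projection_stack(data, p$angles)
}

#' Wavelet-Fourier ring suppression
#'
#' Classical sinogram-domain stripe filter: each sinogram is decomposed
#' with a multilevel 2D wavelet transform; at every level the detail band
#' containing vertical stripes (lowpass along the angle axis, highpass
#' along the detector axis) is Fourier-transformed along the angle axis and
#' multiplied by the damping function `g(k) = 1 - exp(-k^2 / (2 sigma^2))`,
#' which suppresses angle-constant (ring) components; the sinogram is then
#' reassembled.  `sigma = 0` removes only the exactly angle-constant
#' component of each band.
#'
#' @param s A [sinogram_stack()] with at least `2^level` angles.
#' @param level Wavelet decomposition levels (>= 1).
#' @param wname Wavelet name: `"sym5"` (default), `"db2"` or `"haar"`.
#' @param sigma Fourier damping width in frequency-index units (>= 0).
#' @return A filtered [sinogram_stack()] of identical shape.
#' @export
remove_ring_wavelet_fft <- function(s, level = 4L, wname = "sym5", sigma = 8) {
  if (!inherits(s, "sinogram_stack")) stopf("s must be a sinogram_stack")
  if (!is_count(level)) stopf("level must be a positive integer")
  if (!is.numeric(sigma) || sigma < 0) stopf("sigma must be >= 0")
  flt <- wavelet_filters(wname)
  d <- dim(s$data)
  if (d[2] < 2^level)
    stopf("need at least 2^level = %d angles, got %d", 2^level, d[2])
  out <- array(0, dim = d)
  for (m in seq_len(d[1]))
    out[m, , ] <- ring_filter_one(s$data[m, , , drop = TRUE], level, flt, sigma)
  sinogram_stack(out, s$angles)
}

# Filter one sinogram (rows = angles, cols = detector columns).
ring_filter_one <- function(sino, level, flt, sigma) {
  n_a <- nrow(sino)
  n <- ncol(sino)
  # pad (reflect) both axes to multiples of 2^level for the periodized DWT
  blk <- 2^level
  pad_to <- function(n) ceiling(n / blk) * blk
  pa <- pad_to(n_a) - n_a
  pn <- pad_to(n) - n
  x <- sino
  if (pa > 0) x <- rbind(x, x[n_a:(n_a - pa + 1), , drop = FALSE])
  if (pn > 0) x <- cbind(x, x[, n:(n - pn + 1), drop = FALSE])

  damp_band <- function(b) {
    fq <- stats::mvfft(b)
    j <- 0:(nrow(b) - 1)
    k <- pmin(j, nrow(b) - j)
    g <- if (sigma > 0) 1 - exp(-k^2 / (2 * sigma^2)) else as.numeric(k != 0)
    Re(stats::mvfft(fq * g, inverse = TRUE)) / nrow(b)
  }

  decompose <- function(x, lev) {
    bands <- dwt2_step(x, flt)
    bands$ad <- damp_band(bands$ad)
    if (lev > 1) bands$aa <- decompose(bands$aa, lev - 1)
    bands
  }
  reconstruct <- function(bands) {
    if (is.list(bands$aa)) bands$aa <- reconstruct(bands$aa)
    idwt2_step(bands, flt)
  }
  y <- reconstruct(decompose(x, level))
  y[seq_len(n_a), seq_len(n), drop = FALSE]
}

#' Grid search for classical pre-processing parameters
#'
#' Exhaustively evaluates every combination of median-filter and
#' wavelet-Fourier parameters: applies zinger removal then ring removal to
#' the corrupted projections, reconstructs, and scores the mean SSIM
#' against the reference volume.  Returns the argmax (ties broken by first
#' occurrence in grid order) together with the full score table.
#'
#' @param p_corrupt Corrupted [projection_stack()].
#' @param reference Reference 3D volume matching the reconstruction shape.
#' @param grid Named list of candidate values for `dif`, `size`, `level`,
#'   `wname`, `sigma` (each a vector; the grid is their cross product).
#' @return List with `params` (named list of the best combination), `score`
#'   (its mean SSIM) and `table` (data frame of all combinations and
#'   scores).
#' @export
classical_grid_search <- function(p_corrupt, reference, grid) {
  need <- c("dif", "size", "level", "wname", "sigma")
  if (!all(need %in% names(grid)))
    stopf("grid must name all of: %s", paste(need, collapse = ", "))
  tab <- expand.grid(grid[need], stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  if (nrow(tab) == 0L) stopf("empty parameter grid")
  tab$ssim <- NA_real_
  for (i in seq_len(nrow(tab))) {
    pp <- remove_zinger_median(p_corrupt, dif = tab$dif[i], size = tab$size[i])
    ss <- remove_ring_wavelet_fft(rearrange(pp), level = tab$level[i],
                                  wname = tab$wname[i], sigma = tab$sigma[i])
    rec <- fbp_reconstruct(ss)
    tab$ssim[i] <- evaluate_volume(rec, reference)$mean_ssim
  }
  best <- which.max(tab$ssim)
  list(params = as.list(tab[best, need]), score = tab$ssim[best], table = tab)
}
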