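#' Peak signal-to-noise ratio
#'
#' `10 * log10(data_range^2 / MSE)` in dB; returns `Inf` when the images
#' are identical (MSE = 0).
#'
#' @param x,ref Numeric arrays of identical shape.
#' @param data_range Reference dynamic range (> 0).
#' @return PSNR in dB.
#' @export
psnr <- function(x, ref, data_range) {
  if (!identical(dim(x), dim(ref)) || length(x) != length(ref))
    stopf("x and ref must have identical shape")
  if (!is.numeric(data_range) || data_range <= 0)
    stopf("data_range must be > 0")
  mse <- mean((x - ref)^2)
  if (mse == 0) return(Inf)
  10 * log10(data_range^2 / mse)
}

gaussian_kernel_1d <- function(size = 11L, sigma = 1.5) {
  t <- seq_len(size) - (size + 1) / 2
  k <- exp(-t^2 / (2 * sigma^2))
  k / sum(k)
}

#' Structural similarity index
#'
#' Mean local SSIM with the standard 11 x 11 Gaussian window (sigma = 1.5)
#' and stabilizers `C1 = (0.01 * data_range)^2`, `C2 = (0.03 * data_range)^2`,
#' averaged over the valid (fully windowed) region.  A uniform 7 x 7 window
#' (a common software default) is available via `window = "uniform"`.
#'
#' @param x,ref Numeric matrices of identical shape, at least as large as
#'   the window.
#' @param data_range Reference dynamic range (> 0).
#' @param window `"gaussian"` (default) or `"uniform"`.
#' @return SSIM score in `[-1, 1]`.
#' @export
ssim <- function(x, ref, data_range, window = c("gaussian", "uniform")) {
  window <- match.arg(window)
  if (!identical(dim(x), dim(ref))) stopf("x and ref must have identical shape")
  if (!is.numeric(data_range) || data_range <= 0)
    stopf("data_range must be > 0")
  k <- if (window == "gaussian") gaussian_kernel_1d(11L, 1.5) else rep(1 / 7, 7L)
  if (any(dim(x) < length(k)))
    stopf("images must be at least %d x %d", length(k), length(k))
  C1 <- (0.01 * data_range)^2
  C2 <- (0.03 * data_range)^2
  mu1 <- sep_filter_valid_cpp(x, k)
  mu2 <- sep_filter_valid_cpp(ref, k)
  s11 <- sep_filter_valid_cpp(x * x, k) - mu1^2
  s22 <- sep_filter_valid_cpp(ref * ref, k) - mu2^2
  s12 <- sep_filter_valid_cpp(x * ref, k) - mu1 * mu2
  num <- (2 * mu1 * mu2 + C1) * (2 * s12 + C2)
  den <- (mu1^2 + mu2^2 + C1) * (s11 + s22 + C2)
  mean(num / den)
}

#' Evaluate a reconstruction against a high-quality reference
#'
#' Computes per-slice PSNR and SSIM along Z, using the reference volume's
#' global range (`max - min`) as `data_range`, and reports the per-slice
#' lists and their arithmetic means.
#'
#' @param r Reconstructed 3D array `(Z, Y, X)`.
#' @param r_hq Reference 3D array of identical shape.
#' @param reference_id Optional label stored in the report.
#' @return An object of class `eval_report`.
#' @export
evaluate_volume <- function(r, r_hq, reference_id = "reference") {
  if (!identical(dim(r), dim(r_hq)))
    stopf("volumes must have identical shape")
  rng <- max(r_hq) - min(r_hq)
  if (rng <= 0) stopf("reference volume has zero range")
  nz <- dim(r)[1]
  ps <- vapply(seq_len(nz), function(z) psnr(r[z, , ], r_hq[z, , ], rng),
               numeric(1))
  ss <- vapply(seq_len(nz), function(z) ssim(r[z, , ], r_hq[z, , ], rng),
               numeric(1))
  structure(list(psnr = ps, ssim = ss,
                 mean_psnr = mean(ps), mean_ssim = mean(ss),
                 data_range = rng, reference_id = reference_id),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report vs %s: mean PSNR %.2f dB, mean SSIM %.4f (%d slices)\n",
              x$reference_id, x$mean_psnr, x$mean_ssim, length(x$psnr)))
  invisible(x)
}

#' Write / read an evaluation report
#'
#' JSON serialization with full numeric precision; `Inf` PSNR entries (an
#' exact match) survive the round trip as the string sentinel `"Inf"`.
#'
#' @param report An [evaluate_volume()] report.
#' @param path File path.
#' @return `read_eval_report()` returns the restored `eval_report`.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  obj <- unclass(report)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       always_decimal = FALSE)
  invisible(path)
}

#' @rdname write_eval_report
#' @param path File path.
#' @export
read_eval_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$psnr <- as.numeric(obj$psnr)
  obj$ssim <- as.numeric(obj$ssim)
  obj$mean_psnr <- as.numeric(obj$mean_psnr)
  obj$mean_ssim <- as.numeric(obj$mean_ssim)
  structure(obj, class = "eval_report")
}
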