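#' Equally spaced acquisition angles on [0, pi)
#'
#' Parallel-beam scans cover 180 degrees; the endpoint is excluded because a
#' projection at pi duplicates the mirrored projection at 0.
#'
#' @param n_angles Number of angles (>= 1).
#' @return Numeric vector of strictly increasing angles in radians.
#' @export
angle_set <- function(n_angles) {
  if (!is_count(n_angles)) stopf("n_angles must be a positive integer")
  (seq_len(n_angles) - 1) * pi / n_angles
}

#' Projection stack
#'
#' A set of post-log parallel-beam projection images: `data[a, m, n]` is the
#' line integral at angle `a`, detector row `m` (= volume slice) and detector
#' column `n`.
#'
#' @param data Numeric array of dim `(N_a, M, N)`.
#' @param angles Acquisition angles in radians, length `N_a`, strictly
#'   increasing within `[0, pi)`.
#' @return An object of class `projection_stack` with elements `data`, `angles`.
#' @export
projection_stack <- function(data, angles) {
  if (length(dim(data)) != 3L) stopf("projection data must be a 3D array")
  if (dim(data)[1] != length(angles))
    stopf("first dimension (%d) must equal the number of angles (%d)",
          dim(data)[1], length(angles))
  check_angles(angles)
  if (!all(is.finite(data))) stopf("projection data must be finite")
  structure(list(data = data, angles = as.numeric(angles)),
            class = "projection_stack")
}

#' Sinogram stack
#'
#' Rearranged projections: `data[m, a, n]` equals the originating
#' projection element `p[a, m, n]`; each `data[m, , ]` is the sinogram of
#' detector row `m`.
#'
#' @param data Numeric array of dim `(M, N_a, N)`.
#' @param angles Acquisition angles in radians, length `N_a`.
#' @return An object of class `sinogram_stack` with elements `data`, `angles`.
#' @export
sinogram_stack <- function(data, angles) {
  if (length(dim(data)) != 3L) stopf("sinogram data must be a 3D array")
  if (dim(data)[2] != length(angles))
    stopf("second dimension (%d) must equal the number of angles (%d)",
          dim(data)[2], length(angles))
  check_angles(angles)
  if (!all(is.finite(data))) stopf("sinogram data must be finite")
  structure(list(data = data, angles = as.numeric(angles)),
            class = "sinogram_stack")
}

check_angles <- function(angles) {
  if (length(angles) < 1L || any(!is.finite(angles)))
    stopf("angles must be finite and non-empty")
  if (any(angles < 0 | angles >= pi))
    stopf("angles must lie in [0, pi)")
  if (length(angles) > 1L && any(diff(angles) <= 0))
    stopf("angles must be strictly increasing")
  invisible(TRUE)
}

#' @export
print.projection_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("projection_stack: %d angles, %d x %d detector (rows x cols)\n",
              d[1], d[2], d[3]))
  invisible(x)
}

#' @export
print.sinogram_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("sinogram_stack: %d rows, %d angles x %d columns\n",
              d[1], d[2], d[3]))
  invisible(x)
}
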