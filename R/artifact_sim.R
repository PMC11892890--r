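#' Artifact simulation configuration
#'
#' Collects every corruption parameter for [corrupt()].  All `P_*` values
#' are fractions in `[0, 1]` (e.g. `P_ring = 0.1` marks 10% of detector
#' pixels); counts are made exact by rounding (`round(P * count)` elements
#' drawn without replacement), so corruption is assertable rather than
#' Bernoulli-random.
#'
#' @param I0 Incident photon count per detector pixel (> 0 when noise is
#'   enabled).  Lower values mean stronger Poisson noise.
#' @param gamma_target Target mean absorbed photon fraction used by
#'   [calibrate_absorption()] (about half the photons by default).
#' @param P_ring Fraction of detector pixels given a fixed additive offset
#'   (identical in every projection; appears as straight sinogram stripes
#'   and reconstruction rings).
#' @param sigma_ring Standard deviation of the ring offsets.
#' @param P_proj Fraction of projections containing zingers.
#' @param P_zinger Fraction of pixels set to `v` within an affected
#'   projection.
#' @param v Zinger value (detector saturation level in attenuation units).
#' @param seed Integer seed; deterministic sub-seeds are derived per artifact.
#' @param noise,ring,zinger Enable flags per artifact.
#' @return An object of class `artifact_config`.
#' @export
artifact_config <- function(I0 = 100, gamma_target = 0.5, P_ring = 0.1,
                            sigma_ring = 0.005, P_proj = 0.1,
                            P_zinger = 0.001, v = 5, seed = 1L,
                            noise = TRUE, ring = TRUE, zinger = TRUE) {
  for (nm in c("P_ring", "P_proj", "P_zinger")) {
    val <- get(nm)
    if (!is.numeric(val) || val < 0 || val > 1)
      stopf("%s must be a fraction in [0, 1]", nm)
  }
  if (noise && (!is.numeric(I0) || I0 <= 0)) stopf("I0 must be > 0")
  if (sigma_ring < 0) stopf("sigma_ring must be >= 0")
  if (!is.finite(v)) stopf("v must be finite")
  if (gamma_target <= 0 || gamma_target >= 1)
    stopf("gamma_target must be in (0, 1)")
  structure(list(I0 = I0, gamma_target = gamma_target, P_ring = P_ring,
                 sigma_ring = sigma_ring, P_proj = P_proj,
                 P_zinger = P_zinger, v = v, seed = as.integer(seed),
                 noise = noise, ring = ring, zinger = zinger),
            class = "artifact_config")
}

#' Calibrate the mean photon absorption
#'
#' Finds a single global scale `c` such that the mean absorbed fraction
#' `mean(1 - exp(-c * p))` over rays intersecting the object (`p > 0`)
#' equals `gamma_target`, by bisection to within 1e-6, and returns the
#' scaled stack together with `c`.
#'
#' @param p A [projection_stack()] with non-negative, not all-zero data.
#' @param gamma_target Target mean absorbed fraction in (0, 1).
#' @return List with elements `p` (scaled [projection_stack()]) and
#'   `scale` (the factor `c`).
#' @export
calibrate_absorption <- function(p, gamma_target = 0.5) {
  if (!inherits(p, "projection_stack")) stopf("p must be a projection_stack")
  if (any(p$data < 0)) stopf("projections must be non-negative")
  vals <- p$data[p$data > 0]
  if (length(vals) == 0L) stopf("all-zero projections cannot be calibrated")
  f <- function(cc) mean(1 - exp(-cc * vals)) - gamma_target
  lo <- 0
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  repeat {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) < 1e-6 && (hi - lo) < 1e-9 * max(hi, 1)) break
    if (fm < 0) lo <- mid else hi <- mid
    if (hi - lo < .Machine$double.eps * max(hi, 1)) break
  }
  list(p = projection_stack(p$data * mid, p$angles), scale = mid)
}

#' Apply Poisson photon noise
#'
#' Converts post-log attenuation values to expected photon counts
#' `I0 * exp(-p)`, draws Poisson counts per pixel (a Gaussian approximation
#' is used for expected counts above 1e7, where it is accurate to far below
#' the quantization of interest), clips counts below at 1, and returns the
#' re-logged projections `-log(k / I0)`.
#'
#' @param p A [projection_stack()] with non-negative (calibrated) data.
#' @param I0 Incident photon count (> 0).
#' @param seed Integer seed; identical seeds give identical noise.
#' @return A [projection_stack()].
#' @export
apply_poisson <- function(p, I0, seed = 1L) {
  if (!inherits(p, "projection_stack")) stopf("p must be a projection_stack")
  if (!is.numeric(I0) || I0 <= 0) stopf("I0 must be > 0")
  if (any(p$data < 0)) stopf("projections must be non-negative")
  lam <- I0 * exp(-p$data)
  k <- with_seed(seed, {
    out <- numeric(length(lam))
    big <- lam > 1e7
    if (any(!big)) out[!big] <- stats::rpois(sum(!big), lam[!big])
    if (any(big)) out[big] <- round(lam[big] + sqrt(lam[big]) *
                                      stats::rnorm(sum(big)))
    out
  })
  k <- pmax(k, 1)
  noisy <- array(log(I0) - log(k), dim = dim(p$data))
  projection_stack(noisy, p$angles)
}

#' Ring offset pattern
#'
#' Draws a fixed per-detector-pixel offset field `d_ring = M(P_ring) * g`
#' with `g ~ N(0, sigma_ring^2)`: exactly `round(P_ring * M * N)` pixels
#' (chosen without replacement) receive a nonzero offset.
#'
#' @param M,N Detector rows and columns.
#' @param P_ring Fraction of affected pixels in `[0, 1]`.
#' @param sigma_ring Offset standard deviation (>= 0).
#' @param seed Integer seed.
#' @return An object of class `ring_pattern` with fields `offsets`
#'   (`M x N` matrix) and `mask` (logical `M x N`).
#' @export
make_ring_pattern <- function(M, N, P_ring, sigma_ring = 0.005, seed = 1L) {
  if (!is_count(M) || !is_count(N)) stopf("M and N must be positive integers")
  if (P_ring < 0 || P_ring > 1) stopf("P_ring must be in [0, 1]")
  if (sigma_ring < 0) stopf("sigma_ring must be >= 0")
  n_aff <- round(P_ring * M * N)
  offsets <- matrix(0, M, N)
  mask <- matrix(FALSE, M, N)
  if (n_aff > 0) {
    with_seed(seed, {
      idx <- sample.int(M * N, n_aff)
      offsets[idx] <- stats::rnorm(n_aff, 0, sigma_ring)
      mask[idx] <- TRUE
    })
  }
  structure(list(offsets = offsets, mask = mask), class = "ring_pattern")
}

#' Apply ring offsets to projections
#'
#' Adds the identical offset field to every projection image, emulating
#' systematic (miscalibrated) detector elements.
#'
#' @param p A [projection_stack()].
#' @param pattern A [make_ring_pattern()] whose shape matches the detector.
#' @return A [projection_stack()].
#' @export
apply_ring <- function(p, pattern) {
  if (!inherits(p, "projection_stack")) stopf("p must be a projection_stack")
  if (!inherits(pattern, "ring_pattern")) stopf("pattern must be a ring_pattern")
  d <- dim(p$data)
  if (!all(dim(pattern$offsets) == d[2:3]))
    stopf("ring pattern is %d x %d but the detector is %d x %d",
          nrow(pattern$offsets), ncol(pattern$offsets), d[2], d[3])
  add <- aperm(array(pattern$offsets, dim = c(d[2], d[3], d[1])), c(3, 1, 2))
  projection_stack(p$data + add, p$angles)
}

#' Apply zinger outliers
#'
#' Selects exactly `round(P_proj * N_a)` projections without replacement;
#' within each, exactly `round(P_zinger * M * N)` pixels (independently
#' drawn per projection) are set to the saturation value `v`.  All other
#' pixels are untouched.
#'
#' @param p A [projection_stack()].
#' @param P_proj Fraction of affected projections.
#' @param P_zinger Fraction of affected pixels within those projections.
#' @param v Replacement value.
#' @param seed Integer seed.
#' @return A [projection_stack()].
#' @export
apply_zinger <- function(p, P_proj, P_zinger, v = 5, seed = 1L) {
  if (!inherits(p, "projection_stack")) stopf("p must be a projection_stack")
  if (P_proj < 0 || P_proj > 1 || P_zinger < 0 || P_zinger > 1)
    stopf("P_proj and P_zinger must be fractions in [0, 1]")
  d <- dim(p$data)
  n_proj <- round(P_proj * d[1])
  n_pix <- round(P_zinger * d[2] * d[3])
  if (n_proj == 0L || n_pix == 0L) return(p)
  data <- p$data
  with_seed(seed, {
    projs <- sample.int(d[1], n_proj)
    for (a in projs) {
      img <- data[a, , ]
      img[sample.int(d[2] * d[3], n_pix)] <- v
      data[a, , ] <- img
    }
  })
  projection_stack(data, p$angles)
}

#' Corrupt clean projections with the full artifact model
#'
#' Applies, in order: Poisson noise (photon-count domain), ring offsets and
#' zingers (both in the post-log attenuation domain; zingers overwrite,
#' modelling detector saturation).  Steps are skipped when disabled; each
#' step uses a sub-seed derived deterministically from `cfg$seed`.  The
#' input is expected to be absorption-calibrated (see
#' [calibrate_absorption()]).
#'
#' @param p_clean A calibrated [projection_stack()].
#' @param cfg An [artifact_config()].
#' @return A corrupted [projection_stack()].
#' @export
corrupt <- function(p_clean, cfg) {
  if (!inherits(cfg, "artifact_config")) stopf("cfg must be an artifact_config")
  p <- p_clean
  if (cfg$noise)
    p <- apply_poisson(p, cfg$I0, seed = sub_seed(cfg$seed, 1L))
  if (cfg$ring && cfg$P_ring > 0) {
    d <- dim(p$data)
    pat <- make_ring_pattern(d[2], d[3], cfg$P_ring, cfg$sigma_ring,
                             seed = sub_seed(cfg$seed, 2L))
    p <- apply_ring(p, pat)
  }
  if (cfg$zinger && cfg$P_proj > 0 && cfg$P_zinger > 0)
    p <- apply_zinger(p, cfg$P_proj, cfg$P_zinger, cfg$v,
                      seed = sub_seed(cfg$seed, 3L))
  p
}
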