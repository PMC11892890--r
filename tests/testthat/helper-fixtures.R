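# Shared fixtures, built in code.  Expensive objects are memoized so the
# suite constructs each of them once.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# A small foam phantom used by several suites.
tiny_foam <- function() memo("tiny_foam", function() {
  generate_foam_phantom(foam_spec(grid_size = 32L, n_bubbles = 12L,
                                  bubble_radius_range = c(1.5, 4),
                                  seed = 5L))
})

# A small paired scan (clean HQ + corrupted LQ) of the tiny foam.
tiny_scan <- function() memo("tiny_scan", function() {
  simulate_paired_scan(tiny_foam(), n_angles_lq = 8L, factor = 2L,
                       artifact_config(I0 = 1000, P_ring = 0.05,
                                       P_zinger = 0.01, seed = 3L))
})

# Identity pipelines for pass-through contracts.
identity_pipeline <- function(factor = 2L, bypass = TRUE) {
  if (bypass)
    pipeline_models(identity_stage_model(1L), identity_stage_model(2L),
                    identity_stage_model(3L), upsample_factor = factor)
  else
    pipeline_models(identity_stage_model(1L), identity_stage_model(1L),
                    identity_stage_model(1L), upsample_factor = factor,
                    bypass = FALSE)
}

# Independent sliding-window SSIM oracle (direct windowed formula, 11x11
# Gaussian sigma 1.5), kept free of the package's filtering code path.
ssim_bruteforce <- function(x, y, dr) {
  t <- (1:11) - 6
  k2 <- outer(exp(-t^2 / 4.5), exp(-t^2 / 4.5))
  k2 <- k2 / sum(k2)
  C1 <- (0.01 * dr)^2; C2 <- (0.03 * dr)^2
  n <- nrow(x)
  vals <- c()
  for (i in 1:(n - 10)) for (j in 1:(n - 10)) {
    wx <- x[i:(i + 10), j:(j + 10)]
    wy <- y[i:(i + 10), j:(j + 10)]
    m1 <- sum(k2 * wx); m2 <- sum(k2 * wy)
    v1 <- sum(k2 * wx^2) - m1^2
    v2 <- sum(k2 * wy^2) - m2^2
    cv <- sum(k2 * wx * wy) - m1 * m2
    vals <- c(vals, ((2 * m1 * m2 + C1) * (2 * cv + C2)) /
                ((m1^2 + m2^2 + C1) * (v1 + v2 + C2)))
  }
  mean(vals)
}

# Bilinear polar resampling of a square image about its center.
polar_samples <- function(img, radii, phis) {
  c0 <- (nrow(img) - 1) / 2
  outer(radii, phis, function(r, ph) {
    x <- r * cos(ph) + c0
    y <- r * sin(ph) + c0
    x0 <- floor(x); y0 <- floor(y); fx <- x - x0; fy <- y - y0
    img[cbind(y0 + 1, x0 + 1)] * (1 - fx) * (1 - fy) +
      img[cbind(y0 + 1, x0 + 2)] * fx * (1 - fy) +
      img[cbind(y0 + 2, x0 + 1)] * (1 - fx) * fy +
      img[cbind(y0 + 2, x0 + 2)] * fx * fy
  })
}

# Random projection stack.
random_projections <- function(n_a, M, N, seed = 1L) {
  set.seed(seed)
  projection_stack(array(stats::runif(n_a * M * N), dim = c(n_a, M, N)),
                   angle_set(n_a))
}
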