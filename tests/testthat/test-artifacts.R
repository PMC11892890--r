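test_that("absorption calibration solves for the global scale", {
  # fixed point: mean transmission already at target
  p <- projection_stack(array(log(2), dim = c(2, 4, 4)), angle_set(2))
  expect_equal(calibrate_absorption(p, 0.5)$scale, 1, tolerance = 1e-6)
  # closed form: 1 - exp(-c) = 0.5  =>  c = ln 2
  p1 <- projection_stack(array(1, dim = c(2, 4, 4)), angle_set(2))
  expect_equal(calibrate_absorption(p1, 0.5)$scale, log(2), tolerance = 1e-6)
  # scaling identity: doubling p halves c
  p2 <- projection_stack(array(2, dim = c(2, 4, 4)), angle_set(2))
  expect_equal(calibrate_absorption(p2, 0.5)$scale, log(2) / 2,
               tolerance = 1e-6)
  # achieved mean absorption over object rays
  vol <- tiny_foam()
  pf <- forward_project(vol, angle_set(8))
  cal <- calibrate_absorption(pf, 0.5)
  vals <- cal$p$data[cal$p$data > 0]
  expect_equal(mean(1 - exp(-vals)), 0.5, tolerance = 1e-6)
  expect_error(calibrate_absorption(
    projection_stack(array(0, dim = c(2, 4, 4)), angle_set(2))), "zero")
})

test_that("Poisson noise vanishes in the large-count limit and clips at 1", {
  set.seed(1)
  p <- projection_stack(array(runif(2 * 8 * 8, 0, 5), dim = c(2, 8, 8)),
                        angle_set(2))
  pn <- apply_poisson(p, 1e12, seed = 3L)
  expect_lt(max(abs(pn$data - p$data)), 1e-3)
  # count clipped to 1: p = 50, I0 = 100 gives p' = ln(100)
  pz <- projection_stack(array(50, dim = c(1, 4, 4)), angle_set(1))
  expect_equal(unique(as.numeric(apply_poisson(pz, 100, 2L)$data)), log(100))
  expect_error(apply_poisson(p, 0), "I0")
  # same seed, same noise
  expect_identical(apply_poisson(p, 100, 7L), apply_poisson(p, 100, 7L))
})

test_that("noisy log-projections match the analytic clipped-Poisson mean", {
  # Monte-Carlo oracle at p = 0, I0 = 100: E[-log(max(k,1)/I0)], k ~ Poi(I0)
  I0 <- 100
  n <- 1e5
  p <- projection_stack(array(0, dim = c(1, 250, 400)), angle_set(1))
  draws <- apply_poisson(p, I0, seed = 11L)$data
  k <- 0:400
  exact <- sum(stats::dpois(k, I0) * (log(I0) - log(pmax(k, 1))))
  se <- stats::sd(draws) / sqrt(n)
  expect_lt(abs(mean(draws) - exact), 3 * se)
})

test_that("ring patterns affect exactly round(P_ring*M*N) pixels", {
  pat <- make_ring_pattern(100L, 100L, 0.1, 0.005, seed = 5L)
  expect_identical(sum(pat$mask), 1000L)
  expect_true(all(pat$offsets[!pat$mask] == 0))
  # law of large numbers on the offset spread at sigma_ring = 0.005
  pat2 <- make_ring_pattern(200L, 100L, 0.9, 0.005, seed = 6L)
  expect_lt(abs(stats::sd(pat2$offsets[pat2$mask]) - 0.005) / 0.005, 0.10)
  # P_ring = 0 leaves projections untouched
  p <- random_projections(4, 8, 8)
  pat0 <- make_ring_pattern(8L, 8L, 0, 0.005, seed = 1L)
  expect_identical(apply_ring(p, pat0)$data, p$data)
  expect_error(apply_ring(p, make_ring_pattern(4L, 4L, 0.1)), "pattern is")
})

test_that("every projection receives the identical ring offsets", {
  p <- random_projections(6, 10, 12)
  pat <- make_ring_pattern(10L, 12L, 0.2, 0.005, seed = 2L)
  pr <- apply_ring(p, pat)
  for (a in 1:6)
    expect_equal(pr$data[a, , ] - p$data[a, , ], pat$offsets,
                 tolerance = 1e-12)
})

test_that("ring corruption commutes with rearrangement", {
  p <- random_projections(5, 6, 7)
  pat <- make_ring_pattern(6L, 7L, 0.3, 0.01, seed = 4L)
  a <- rearrange(apply_ring(p, pat))$data
  # apply in sinogram space: add offsets[m, n] to every angle of row m
  s <- rearrange(p)$data
  for (m in 1:6) for (n in 1:7) s[m, , n] <- s[m, , n] + pat$offsets[m, n]
  expect_identical(a, s)
})

test_that("zingers change exactly the prescribed projections and pixels", {
  p <- random_projections(100, 10, 10, seed = 8L)
  pz <- apply_zinger(p, 0.1, 0.05, v = 5, seed = 9L)
  changed_proj <- which(apply(pz$data != p$data, 1, any))
  expect_length(changed_proj, 10L)  # round(0.1 * 100)
  for (a in changed_proj) {
    diff_idx <- which(pz$data[a, , ] != p$data[a, , ])
    expect_length(diff_idx, 5L)     # round(0.05 * 100)
    expect_true(all(pz$data[a, , ][diff_idx] == 5))
  }
  # total changed-pixel count is the exact product
  expect_identical(sum(pz$data != p$data), 50L)
  expect_identical(apply_zinger(p, 0, 0.5)$data, p$data)
})

test_that("corrupt() composes artifacts deterministically", {
  p <- random_projections(8, 16, 16)
  off <- artifact_config(noise = FALSE, ring = FALSE, zinger = FALSE)
  expect_identical(corrupt(p, off)$data, p$data)
  cfg <- artifact_config(I0 = 100, P_ring = 0.1, P_zinger = 0.001,
                         P_proj = 0.1, v = 5, seed = 13L)
  expect_identical(corrupt(p, cfg), corrupt(p, cfg))
  # ring-only corruption is constant along the angle axis in every column
  ring_cfg <- artifact_config(P_ring = 0.2, noise = FALSE, zinger = FALSE,
                              seed = 14L)
  dif <- rearrange(corrupt(p, ring_cfg))$data - rearrange(p)$data
  spread <- apply(dif, c(1, 3), function(v) diff(range(v)))
  expect_lt(max(spread), 1e-12)
})

test_that("reconstructed ring-only corruption is concentric", {
  # Polar transform of fbp(ring noise): angular variance << radial variance
  # within the angular range the scan covers.  A 180-degree parallel-beam
  # scan turns a constant detector offset at signed position d into an arc
  # of radius |d| whose tangent points sweep half the circle (upper half
  # for d > 0), so concentricity is assessed over that half.
  M <- 1L; N <- 64L; n_a <- 64L
  pat <- make_ring_pattern(M, N, 0.2, 0.05, seed = 21L)
  pat$offsets[, 1:(N / 2 + 1)] <- 0   # keep offsets with d > 0 only
  p0 <- projection_stack(array(0, dim = c(n_a, M, N)), angle_set(n_a))
  nr <- fbp_reconstruct(rearrange(apply_ring(p0, pat)))[1, , ]
  polar <- polar_samples(nr, seq(2, N / 2 - 4, by = 0.5),
                         seq(0.2 * pi, 0.8 * pi, length.out = 60))
  radial_mean <- rowMeans(polar)
  angular_var <- mean((polar - radial_mean)^2)
  radial_var <- mean((radial_mean - mean(radial_mean))^2)
  expect_lt(angular_var / radial_var, 0.1)
})

test_that("invalid artifact configurations are rejected", {
  expect_error(artifact_config(P_ring = 1.2), "fraction")
  expect_error(artifact_config(I0 = -1), "I0")
  expect_error(artifact_config(sigma_ring = -0.1), "sigma_ring")
})
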