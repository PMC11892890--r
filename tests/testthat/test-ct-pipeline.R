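test_that("forward projection of a zero volume is zero", {
  vol <- array(0, dim = c(2, 16, 16))
  p <- forward_project(vol, angle_set(8))
  expect_true(all(p$data == 0))
})

test_that("disk projections match the analytic chord length", {
  R <- 20; mu <- 1.5
  vol <- generate_disk_phantom(64, R, mu)[1, , , drop = FALSE]
  p <- forward_project(vol, angle_set(32))
  # central detector column: full diameter chord 2*R*mu at every angle
  central <- p$data[, 1, 32]  # detector coordinate closest to d = -0.5
  chord <- 2 * mu * sqrt(R^2 - 0.5^2)
  expect_true(all(abs(central - chord) / chord < 0.03))
})

test_that("an off-center point traces the analytic sinusoid", {
  vol <- array(0, dim = c(1, 64, 64))
  vol[1, 20, 40] <- 1
  angles <- angle_set(64)
  p <- forward_project(vol, angles)
  c0 <- (64 - 1) / 2
  x0 <- 39 - c0; y0 <- 19 - c0
  predicted <- x0 * cos(angles) + y0 * sin(angles) + c0
  observed <- apply(p$data[, 1, ], 1, which.max) - 1
  expect_true(all(abs(observed - predicted) <= 1))
})

test_that("projections scale linearly with the volume", {
  vol <- tiny_foam()
  a <- forward_project(vol, angle_set(4))
  b <- forward_project(2.5 * vol, angle_set(4))
  expect_equal(b$data, 2.5 * a$data, tolerance = 1e-12)
})

test_that("rearrange permutes axes losslessly", {
  p <- random_projections(256, 4, 4)
  s <- rearrange(p)
  expect_identical(dim(s$data), c(4L, 256L, 4L))
  expect_identical(inverse_rearrange(s)$data, p$data)
  # element mapping
  p$data[3, 4, 2] <- 0.42
  expect_identical(rearrange(p)$data[4, 3, 2], 0.42)
})

test_that("angle upsampling has the right count, identity and affine behavior", {
  p <- random_projections(256, 2, 4)
  s <- rearrange(p)
  expect_identical(angle_upsample(s, 1L)$data, s$data)
  s4 <- angle_upsample(s, 4L)
  expect_identical(dim(s4$data)[2], 1024L)
  expect_error(angle_upsample(s, 0L), "factor")
  expect_error(angle_upsample(s, 2.5), "factor")
  # values affine in the angle index are reproduced exactly in the interior
  n_a <- 16L
  lin <- sinogram_stack(array(rep(2 * (1:n_a) + 1, each = 1),
                              dim = c(1, n_a, 3)), angle_set(n_a))
  for (a in seq_len(n_a)) lin$data[1, a, ] <- 2 * a + 1
  up <- angle_upsample(lin, 4L)
  interior <- seq_len(4L * (n_a - 1L) + 1L)
  expect_equal(up$data[1, interior, 2],
               2 * seq(1, n_a, by = 0.25) + 1, tolerance = 1e-12)
})

test_that("FBP reconstructs zero from zero and recovers a disk", {
  z <- sinogram_stack(array(0, dim = c(1, 8, 16)), angle_set(8))
  expect_true(all(fbp_reconstruct(z) == 0))
  expect_error(fbp_reconstruct(sinogram_stack(array(0, dim = c(1, 1, 8)),
                                              angle_set(1))), "angles")
  # round-trip oracle
  vol <- generate_disk_phantom(128, 40, 1)[1, , , drop = FALSE]
  r <- fbp_reconstruct(rearrange(forward_project(vol, angle_set(256))))
  c0 <- (128 - 1) / 2
  xy <- (0:127) - c0
  inside <- outer(xy^2, xy^2, "+") <= (64 - 6)^2
  rel_rmse <- sqrt(mean((r[1, , ][inside] - vol[1, , ][inside])^2))
  expect_lt(rel_rmse, 0.05)
})

test_that("FBP is linear (superposition of sinograms)", {
  set.seed(2)
  s1 <- sinogram_stack(array(rnorm(2 * 16 * 24), dim = c(2, 16, 24)),
                       angle_set(16))
  s2 <- sinogram_stack(array(rnorm(2 * 16 * 24), dim = c(2, 16, 24)),
                       angle_set(16))
  r12 <- fbp_reconstruct(sinogram_stack(s1$data + s2$data, s1$angles))
  r1 <- fbp_reconstruct(s1)
  r2 <- fbp_reconstruct(s2)
  expect_lt(max(abs(r12 - (r1 + r2))) / max(abs(r12)), 1e-4)
})

test_that("an angle-constant sinogram column reconstructs to a ring arc", {
  # the ring-artifact mechanism: a constant stripe at detector offset d
  # backprojects to an arc of radius |d| that is rotationally symmetric
  # over the half-circle a 180-degree scan covers
  sino <- array(0, dim = c(1, 64, 64))
  sino[1, , 46] <- 1  # d = 45 - 31.5 = +13.5, arc in the upper half
  r <- fbp_reconstruct(sinogram_stack(sino, angle_set(64)))[1, , ]
  polar <- polar_samples(r, seq(2, 28, by = 0.5),
                         seq(0.2 * pi, 0.8 * pi, length.out = 60))
  # radial profiles at well-separated polar angles are nearly identical
  expect_gt(stats::cor(polar[, 1], polar[, 60]), 0.9)
  expect_gt(stats::cor(polar[, 15], polar[, 45]), 0.9)
})

test_that("non-square slices are rejected", {
  expect_error(forward_project(array(0, dim = c(2, 8, 10)), angle_set(4)),
               "square")
})
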