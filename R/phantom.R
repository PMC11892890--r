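#' Foam phantom specification
#'
#' Describes a cylindrical foam test object: a solid cylinder of uniform
#' attenuation `mu_material` containing non-overlapping spherical bubbles of
#' zero attenuation.  Defaults correspond to the full-scale benchmark object
#' (a 512-voxel cube with 100000 bubbles); use [scaled_foam_spec()] for
#' smaller, test-sized variants with a comparable bubble volume fraction.
#'
#' Bubble centers are drawn uniformly inside the cylinder, radii log-uniformly
#' in `bubble_radius_range` (voxels), and candidates overlapping an accepted
#' bubble or protruding from the cylinder are rejected.
#'
#' @param grid_size Voxels per side of the cubic grid (>= 8).
#' @param cylinder_radius_frac Cylinder radius as a fraction of the grid
#'   half-width `(grid_size - 1) / 2`.
#' @param n_bubbles Number of bubbles (>= 0).
#' @param bubble_radius_range Length-2 numeric, min and max bubble radius in
#'   voxels; must be smaller than the cylinder radius.
#' @param mu_material Attenuation value of the foam material (per-voxel
#'   units, voxel size 1).
#' @param seed Integer seed; identical seeds give bitwise-identical phantoms.
#' @return An object of class `foam_spec`.
#' @export
foam_spec <- function(grid_size = 512L, cylinder_radius_frac = 0.8,
                      n_bubbles = 100000L, bubble_radius_range = c(1, 5),
                      mu_material = 1, seed = 1L) {
  if (!is_count(grid_size, min = 8)) stopf("grid_size must be an integer >= 8")
  if (!is_count(n_bubbles, min = 0)) stopf("n_bubbles must be an integer >= 0")
  if (cylinder_radius_frac <= 0 || cylinder_radius_frac > 1)
    stopf("cylinder_radius_frac must be in (0, 1]")
  r <- as.numeric(bubble_radius_range)
  if (length(r) != 2L || any(!is.finite(r)) || any(r <= 0) || r[1] > r[2])
    stopf("bubble_radius_range must be two positive numbers (min, max)")
  r_cyl <- cylinder_radius_frac * (grid_size - 1) / 2
  if (r[2] >= r_cyl)
    stopf("max bubble radius (%.3g) must be smaller than the cylinder radius (%.3g)",
          r[2], r_cyl)
  if (mu_material < 0) stopf("mu_material must be >= 0")
  structure(list(grid_size = as.integer(grid_size),
                 cylinder_radius_frac = cylinder_radius_frac,
                 n_bubbles = as.integer(n_bubbles),
                 bubble_radius_range = r,
                 mu_material = mu_material,
                 seed = as.integer(seed)),
            class = "foam_spec")
}

#' Scaled-down foam phantom specification
#'
#' Chooses the bubble count so that the expected bubble volume fraction of
#' the cylinder matches `fill_fraction`, with bubble radii a fixed fraction
#' of the grid size.  This keeps small phantoms visually and statistically
#' comparable to the full-scale object.
#'
#' @param grid_size Voxels per side.
#' @param fill_fraction Target fraction of cylinder volume occupied by
#'   bubbles (default 0.16, matching the full-scale default).
#' @param seed Integer seed.
#' @inheritParams foam_spec
#' @return A `foam_spec`.
#' @export
scaled_foam_spec <- function(grid_size, fill_fraction = 0.16,
                             cylinder_radius_frac = 0.8, mu_material = 1,
                             seed = 1L) {
  rr <- c(0.02, 0.08) * grid_size
  # E[r^3] under a log-uniform radius law
  er3 <- (rr[2]^3 - rr[1]^3) / (3 * log(rr[2] / rr[1]))
  r_cyl <- cylinder_radius_frac * (grid_size - 1) / 2
  v_cyl <- pi * r_cyl^2 * grid_size
  n <- max(1L, round(fill_fraction * v_cyl / (4 / 3 * pi * er3)))
  foam_spec(grid_size = grid_size, cylinder_radius_frac = cylinder_radius_frac,
            n_bubbles = n, bubble_radius_range = rr,
            mu_material = mu_material, seed = seed)
}

#' Generate a foam phantom volume
#'
#' Rejection-samples `n_bubbles` non-overlapping bubbles inside the cylinder
#' (at most `1000 * n_bubbles` candidate draws) and voxelizes the result.
#' Voxels take exactly two values: `mu_material` inside the foam and 0
#' outside the cylinder or inside a bubble.
#'
#' @param spec A [foam_spec()].
#' @return A 3D numeric array with dim `(Z, Y, X)`, the attenuation volume.
#'   Bubble centers/radii are attached as attribute `"bubbles"`.
#' @export
generate_foam_phantom <- function(spec) {
  if (!inherits(spec, "foam_spec")) stopf("spec must be a foam_spec")
  r_cyl <- spec$cylinder_radius_frac * (spec$grid_size - 1) / 2
  bub <- with_seed(spec$seed,
    place_bubbles_cpp(spec$n_bubbles, spec$grid_size, r_cyl,
                      spec$bubble_radius_range[1], spec$bubble_radius_range[2],
                      1000L))
  vol <- voxelize_foam_cpp(spec$grid_size, r_cyl, spec$mu_material,
                           bub$x, bub$y, bub$z, bub$r)
  attr(vol, "bubbles") <- as.data.frame(bub)
  vol
}

#' Generate a uniform disk phantom
#'
#' A single uniform disk of value `mu`, replicated along Z: a minimal
#' analytic object for exercising the projector and reconstruction (chord
#' lengths and disk area are known in closed form).
#'
#' @param grid_size Voxels per side (the volume is `grid_size^3`).
#' @param radius Disk radius in voxels; must satisfy `radius < grid_size / 2`.
#' @param mu Attenuation value inside the disk.
#' @return A 3D numeric array with dim `(Z, Y, X)`.
#' @export
generate_disk_phantom <- function(grid_size, radius, mu = 1) {
  if (!is_count(grid_size, min = 2)) stopf("grid_size must be a positive integer")
  if (!is.numeric(radius) || radius <= 0 || radius >= grid_size / 2)
    stopf("radius must satisfy 0 < radius < grid_size / 2")
  c0 <- (grid_size - 1) / 2
  xy <- (seq_len(grid_size) - 1) - c0
  d2 <- outer(xy^2, xy^2, "+")
  slice <- ifelse(d2 <= radius^2, mu, 0)
  vol <- array(0, dim = c(grid_size, grid_size, grid_size))
  for (z in seq_len(grid_size)) vol[z, , ] <- slice
  vol
}
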