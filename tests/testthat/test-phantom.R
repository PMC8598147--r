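# Voxel phantoms, procedural fixtures, resampling, beam geometry and the
# imaging plane.

test_that("water slab has the right grid, density and mass at any voxel size", {
  p1 <- build_water_slab(20, 40, 1)
  expect_equal(dim(p1$density), c(40L, 40L, 20L))
  expect_true(all(p1$density == 1.0))
  expect_equal(mean(p1$density), 1.0)
  p2 <- build_water_slab(20, 40, 2)
  expect_equal(dim(p2$density), c(20L, 20L, 10L))
  expect_equal(phantom_mass(p2), phantom_mass(p1))  # same total mass
  expect_equal(phantom_mass(p1), 40 * 40 * 20)
  expect_error(build_water_slab(20, 40, 3), "grid-mismatch")
})

test_that("slab entrance sits at SSD and the plane 30 cm below its exit", {
  p <- build_water_slab(20, 40, 1)
  expect_equal(p$origin[3], 90)
  exit_z <- p$origin[3] + dim(p$density)[3] * p$voxel_size
  pl <- imaging_plane(sid = 140)
  expect_equal(pl$distance_from_source - exit_z, 30)
})

test_that("pelvis fixture contains exactly air, soft tissue and bone densities", {
  p <- build_pelvis_like(1)
  expect_equal(sort(unique(as.vector(p$density))), c(0.0012, 1.0, 1.85))
  expect_true(all(c("air", "soft_tissue", "cortical_bone") %in%
                    materials()$name[unique(as.vector(p$material_id))]))
})

test_that("thorax fixture additionally contains lung", {
  p <- build_thorax_like(1)
  expect_equal(sort(unique(as.vector(p$density))), c(0.0012, 0.26, 1.0, 1.85))
  # two disjoint lung volumes in a central slice
  k <- dim(p$density)[3] %/% 2
  lung <- p$density[, k, ] == 0.26
  expect_gt(sum(lung), 0)
})

test_that("fixture mass is stable under voxel-size refinement within 2%", {
  for (build in list(build_pelvis_like, build_thorax_like)) {
    m_fine <- phantom_mass(build(0.25))
    for (h in c(0.5, 1)) {
      expect_lt(abs(phantom_mass(build(h)) - m_fine) / m_fine, 0.02)
    }
  }
})

test_that("resampling: identity, uniform coarsening, checkerboard mean, mass", {
  p <- build_water_slab(20, 40, 0.5)
  expect_identical(resample_phantom(p, 0.5), p)
  pc <- resample_phantom(p, 1)
  expect_true(all(pc$density == 1.0))
  expect_equal(phantom_mass(pc), phantom_mass(p), tolerance = 1e-9)
  # half-bone/half-air checkerboard coarsens to the arithmetic mean density
  d <- array(0, dim = c(4, 4, 4))
  parity <- (slice.index(d, 1) + slice.index(d, 2) + slice.index(d, 3)) %% 2
  dens <- ifelse(parity == 0, 1.85, 0.0012)
  mat <- ifelse(parity == 0, "cortical_bone", "air")
  pchk <- voxel_phantom(dens, mat, 0.5, c(0, 0, 90))
  pck <- resample_phantom(pchk, 1)
  expect_true(all(abs(pck$density - (1.85 + 0.0012) / 2) < 1e-12))
  expect_equal(phantom_mass(pck), phantom_mass(pchk), tolerance = 1e-9)
  # refinement replicates and preserves mass
  pr <- resample_phantom(pchk, 0.25)
  expect_equal(phantom_mass(pr), phantom_mass(pchk), tolerance = 1e-12)
  expect_error(resample_phantom(p, 0.7), "grid-mismatch")
})

test_that("in_field: axis, closed edge, outside, and scale consistency", {
  b <- fixture_beam(4)
  expect_true(in_field(c(0, 0, 100), b))
  expect_true(in_field(c(2, 0, 100), b))       # exactly on the edge (closed)
  expect_false(in_field(c(3, 0, 100), b))      # 1 cm outside a 4x4 field
  expect_true(in_field(c(1.8, 1.8, 90), b))    # divergence: 2*90/100 = 1.8
  expect_false(in_field(c(2.1, 0, 100), b))
  # scaling lateral position with depth preserves membership
  pts <- cbind(1.9 * c(0.9, 1.0, 1.1), 0, 100 * c(0.9, 1.0, 1.1))
  expect_equal(unname(in_field(pts, b)), rep(TRUE, 3))
})

test_that("imaging plane tiles exactly and pixel centers are symmetric", {
  pl <- imaging_plane(extent = 40, pixel_size = 1)
  expect_equal(pl$n_pixels, 40L)
  expect_equal(pl$pixel_centers, -rev(pl$pixel_centers))
  xy <- pixel_coordinates(pl)
  expect_equal(nrow(xy), 1600L)
  expect_equal(unique(xy[, 3]), 140)
  expect_error(imaging_plane(extent = 40, pixel_size = 0.7), "tile")
})

test_that("phantom text container round-trips", {
  p <- build_thorax_like(2)
  d <- tempfile()
  write_phantom(p, d)
  p2 <- read_phantom(d)
  expect_equal(p2$density, p$density)
  expect_equal(p2$material_id, p$material_id)
  expect_equal(p2$voxel_size, p$voxel_size)
  expect_equal(p2$origin, p$origin)
})
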