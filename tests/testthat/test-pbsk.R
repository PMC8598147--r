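# Pencil-beam scatter kernels and the EIG superposition.

test_that("a spectrum entirely below the pair threshold gives a zero kernel", {
  s <- energy_spectrum(c(0.3, 0.9), 1, 0.6)
  k <- generate_kernel(10, 20, s, 2e4, seed = 9, extent = 20)
  expect_true(all(k$ef == 0))
})

test_that("kernel totals are statistically reproducible and grow with thickness", {
  s <- beam_spectrum("18MV", bin_size = 1)
  k5 <- generate_kernel(5, 30, s, 1e5, seed = 51, extent = 40)
  k20 <- generate_kernel(20, 30, s, 1e5, seed = 51, extent = 40)
  t5 <- sum(k5$ef); t20 <- sum(k20$ef)
  expect_gt(t20, t5)   # more interactions per pencil in a thicker slab
  k20b <- generate_kernel(20, 30, s, 1e5, seed = 52, extent = 40)
  expect_lt(abs(sum(k20b$ef) - t20) / t20, 0.2)
})

test_that("the EIG fraction of total scatter increases with beam energy", {
  g <- shared_geometry()
  pl <- g$plane
  b6 <- beam_geometry(10, beam_spectrum("6MV"))
  b18 <- beam_geometry(10, beam_spectrum("18MV"))
  or6 <- run_full_mc_oracle(b6, g$phantom, pl, 1e6, seed = 17)
  or18 <- run_full_mc_oracle(b18, g$phantom, pl, 1e6, seed = 17)
  f6 <- sum(or6$nef$eig) / sum(or6$nef$scatter)
  f18 <- sum(or18$nef$eig) / sum(or18$nef$scatter)
  expect_gt(f18, 1.5 * f6)
})

test_that("bilinear interpolation: node identity, midpoint mean, hand formula, bounds", {
  s <- beam_spectrum("18MV", bin_size = 1)
  lib <- build_kernel_library(s, 2e4, seed = 60,
                              thicknesses = c(10, 20), air_gaps = c(20, 40),
                              extent = 20)
  k_node <- interpolate_kernel(lib, 20, 40)
  expect_equal(k_node$ef, lib$kernels[[2, 2]]$ef)
  k_mid <- interpolate_kernel(lib, 15, 20)
  expect_equal(k_mid$ef, (lib$kernels[[1, 1]]$ef + lib$kernels[[2, 1]]$ef) / 2)
  # general interior point: hand bilinear combination of the 4 node totals
  kq <- interpolate_kernel(lib, 12.5, 35)
  tx <- 0.25; ty <- 0.75
  tot <- function(i, j) sum(lib$kernels[[i, j]]$ef)
  expected <- (1 - tx) * (1 - ty) * tot(1, 1) + tx * (1 - ty) * tot(2, 1) +
    (1 - tx) * ty * tot(1, 2) + tx * ty * tot(2, 2)
  expect_equal(sum(kq$ef), expected, tolerance = 1e-12)
  # bounded element-wise by the surrounding node kernels
  lo <- pmin(lib$kernels[[1, 1]]$ef, lib$kernels[[2, 1]]$ef,
             lib$kernels[[1, 2]]$ef, lib$kernels[[2, 2]]$ef)
  hi <- pmax(lib$kernels[[1, 1]]$ef, lib$kernels[[2, 1]]$ef,
             lib$kernels[[1, 2]]$ef, lib$kernels[[2, 2]]$ef)
  expect_true(all(kq$ef >= lo - 1e-15 & kq$ef <= hi + 1e-15))
  expect_error(interpolate_kernel(lib, 45, 30), "extrapolation-refused")
  expect_error(interpolate_kernel(lib, 15, 10), "extrapolation-refused")
})

test_that("superposition is linear in the kernels and in the incident field", {
  g <- shared_geometry()
  s <- g$spectrum
  lib <- build_kernel_library(s, 5e4, seed = 70,
                              thicknesses = c(10, 30), air_gaps = c(20, 40),
                              extent = 30)
  img1 <- compute_eig_nef(g$phantom, g$beam, g$plane, lib)
  lib2 <- lib
  for (i in 1:2) for (j in 1:2) {
    lib2$kernels[[i, j]]$ef <- 2 * lib$kernels[[i, j]]$ef
    lib2$kernels[[i, j]]$nf <- 2 * lib$kernels[[i, j]]$nf
  }
  img2 <- compute_eig_nef(g$phantom, g$beam, g$plane, lib2)
  expect_equal(img2$values, 2 * img1$values, tolerance = 1e-12)
  expect_true(all(img1$values >= 0))
})

test_that("a delta field deposits one interpolated kernel, scaled", {
  g <- shared_geometry()
  s <- g$spectrum
  lib <- build_kernel_library(s, 5e4, seed = 70,
                              thicknesses = c(10, 30), air_gaps = c(20, 40),
                              extent = 30)
  b <- beam_geometry(0.5, s)                 # one 0.5-cm pencil on the axis
  pl <- imaging_plane(extent = 100, pixel_size = 2, sid = 140)  # capture all
  img <- compute_eig_nef(g$phantom, b, pl, lib)
  expect_equal(img$sampling$n_pencils, 1L)
  # total deposited energy equals the pencil energy times the kernel sum
  kern <- interpolate_kernel(lib, water_equivalent_thickness(c(0, 0, 0), c(0, 0, 140), g$phantom),
                             30)
  z0 <- g$phantom$origin[3]
  e_cell <- spectrum_mean_energy(s) / (4 * pi * z0^2) * 0.5^2
  expected_total <- e_cell * sum(kern$ef) * lib$resolution^2
  got_total <- sum(img$values) * pl$pixel_size^2 * incident_energy_fluence(b)
  expect_equal(got_total, expected_total, tolerance = 1e-9)
})

test_that("coverage policy: refuse or clamp out-of-hull queries", {
  g <- shared_geometry()
  s <- g$spectrum
  lib <- build_kernel_library(s, 2e4, seed = 80,
                              thicknesses = c(30, 40), air_gaps = c(20, 40),
                              extent = 20)   # thickness hull excludes ~20 cm
  expect_error(compute_eig_nef(g$phantom, g$beam, g$plane, lib),
               "library-coverage")
  img <- compute_eig_nef(g$phantom, g$beam, g$plane, lib, coverage = "clamp")
  expect_true(all(is.finite(img$values)))
})
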