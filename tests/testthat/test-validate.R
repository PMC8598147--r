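# Validation metrics, error budget, TH assembly, sweep driver.

test_that("percent-difference summary closed forms", {
  m <- matrix(runif(25, 1, 2), 5, 5)
  p0 <- percent_difference_summary(m, m)
  expect_equal(p0$accuracy, 0)
  expect_equal(p0$precision, 0)
  p1 <- percent_difference_summary(1.01 * m, m)
  expect_equal(p1$accuracy, 1, tolerance = 1e-9)
  expect_equal(p1$precision, 0, tolerance = 1e-9)
  # masking excludes noisy pixels and reports the count
  rs <- matrix(0.001, 5, 5); rs[1, 1] <- 0.5
  pm <- percent_difference_summary(m, m, rel_sigma = rs, max_rel_sigma = 0.01)
  expect_equal(pm$n_excluded, 1L)
  expect_equal(pm$n_included, 24L)
  expect_true(is.na(pm$pdi[1, 1]))
  expect_error(percent_difference_summary(m, m, rel_sigma = rs,
                                          max_rel_sigma = 1e-6),
               "empty-comparison")
})

test_that("rRMSE closed forms", {
  m <- matrix(c(1, 2), 1, 2)
  expect_equal(rrmse(m, m), 0)
  expect_equal(rrmse(1.01 * m, m), 0.01, tolerance = 1e-12)
  th <- matrix(c(1.1, 1.8), 1, 2)
  expect_equal(rrmse(th, m), sqrt((0.01 + 0.01) / 2), tolerance = 1e-12)
  expect_equal(rrmse(th, m), 0.1, tolerance = 1e-12)
  expect_error(rrmse(th, matrix(c(0, 2), 1, 2)), "zero gold-standard")
})

test_that("efficiency figure of merit", {
  expect_equal(efficiency(1, 1)$epsilon, 1)
  expect_equal(efficiency(4, 0.5)$epsilon, 1)
  e <- efficiency(78.7, 0.0012)
  expect_equal(e$epsilon, 1 / (78.7 * 0.0012^2), tolerance = 1e-12)
  expect_error(efficiency(0, 1), "> 0")
  expect_error(efficiency(1, -1), "> 0")
  # strictly decreasing in each argument
  expect_gt(efficiency(1, 0.5)$epsilon, efficiency(2, 0.5)$epsilon)
  expect_gt(efficiency(2, 0.4)$epsilon, efficiency(2, 0.5)$epsilon)
})

test_that("error budget reproduces the component tolerances", {
  eb <- error_budget(c(single = 0.70, multiple = 0.20, eig = 0.10), 1)
  expect_equal(round(unname(eb$tolerances), 1), c(1.4, 5, 10))
  expect_equal(eb$sigma_total, sqrt(3), tolerance = 1e-12)
  expect_equal(round(eb$sigma_total, 1), 1.7)
  eb2 <- error_budget(c(all = 1), 2)
  expect_equal(unname(eb2$tolerances), 2)
  expect_equal(eb2$sigma_total, 2)
  expect_error(error_budget(c(0.5, 0.2, 0.1)), "sum to 1")
  expect_error(error_budget(c(0.9, 0.1, 0)), "> 0")
})

test_that("mean-energy overlap: identity, disjoint, symmetry, shift invariance", {
  a <- matrix(runif(100, 1, 2), 10, 10)
  expect_equal(mean_energy_overlap(a, a), 1)
  b <- a + 5
  expect_equal(mean_energy_overlap(a, b), 0)
  c2 <- matrix(runif(100, 1.2, 2.2), 10, 10)
  expect_equal(mean_energy_overlap(a, c2), mean_energy_overlap(c2, a))
  # shifting both images by a whole number of bins leaves the overlap alone
  expect_equal(mean_energy_overlap(a + 0.05 * 7, c2 + 0.05 * 7),
               mean_energy_overlap(a, c2), tolerance = 1e-9)
})

test_that("recommended settings switch voxel size at the 10x10 field", {
  expect_equal(recommended_settings(4)$voxel_size, 0.5)
  expect_equal(recommended_settings(10)$voxel_size, 1)
  expect_equal(recommended_settings(20)$voxel_size, 1)
  s <- recommended_settings(10)
  expect_equal(s$energy_bin_size, 1)
  expect_equal(s$mchhb, 20000)
  expect_equal(s$order_range, c(2, Inf))
  expect_equal(s$pbsk_resolution, 0.5)
})

test_that("tri-hybrid total equals the pixel-wise sum of its components", {
  th <- shared_th()
  expect_identical(th$total$values,
                   th$single$values + th$multiple$values + th$eig$values)
  expect_true(all(th$total$values >= 0))
  expect_true(all(is.finite(th$timings)))
})

test_that("sweep driver: single-cell table, metrics filled, bad keys rejected", {
  g <- shared_geometry()
  ref <- compute_single_scatter_nef(g$phantom, g$beam, g$plane,
                                    voxel_size = 1, energy_bin_size = 1)
  cfg <- list(phantom = g$phantom, beam = g$beam, plane = g$plane,
              cells = data.frame(voxel_size = 2, energy_bin_size = 1),
              reference = ref, components = "single")
  tab <- run_sampling_sweep(cfg)
  expect_equal(nrow(tab), 1L)
  expect_true(all(c("accuracy", "precision", "rrmse", "t_cpu", "epsilon")
                  %in% names(tab)))
  expect_true(is.finite(tab$rrmse) && tab$rrmse > 0)
  expect_equal(tab$epsilon, 1 / (tab$t_cpu * tab$rrmse^2), tolerance = 1e-6)
  f <- tempfile(fileext = ".csv")
  run_sampling_sweep(cfg, csv = f)
  expect_true(file.exists(f))
  cfg$bogus <- 1
  expect_error(run_sampling_sweep(cfg), "invalid config keys")
  expect_error(run_sampling_sweep(list(cells = cfg$cells)), "missing keys")
})

test_that("NEF container and profile export round-trip", {
  th <- shared_th()
  d <- tempfile()
  write_nef(th$single, d)
  back <- read_nef(d)
  expect_equal(back$values, th$single$values, tolerance = 1e-12)
  expect_equal(back$component, "single")
  pr <- nef_profiles(th$total)
  expect_equal(nrow(pr), th$total$plane$n_pixels)
  expect_true(all(c("position_cm", "cross_plane", "in_plane") %in% names(pr)))
})
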