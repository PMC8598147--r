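# The tagging Monte Carlo engine: sources, transport, records, tallies.

test_that("stochastic entry points demand an explicit seed", {
  g <- shared_geometry()
  expect_error(run_phase_space_extraction(g$beam, g$phantom, 10),
               "missing-seed")
  expect_error(run_full_mc_oracle(g$beam, g$phantom, g$plane, 10),
               "missing-seed")
  expect_error(transport_history(g$beam, g$phantom), "missing-seed")
})

test_that("vacuum phantom: no records, photons cross with order 0", {
  vac <- voxel_phantom(array(0, c(20, 20, 10)), "water", 2, c(-20, -20, 90))
  b <- fixture_beam(10)
  th <- transport_history(b, vac, seed = 5, n_histories = 200)
  expect_equal(nrow(th$records), 0L)
  expect_true(all(th$history[, "n_compton"] == 0))
  crossed <- !is.na(th$history[, "exit_order"])
  expect_true(all(th$history[crossed, "exit_order"] == 0))
  or <- run_full_mc_oracle(b, vac, fixture_plane(), 1000, seed = 5)
  expect_true(all(or$nef$single == 0))
  expect_true(all(or$nef$multiple == 0))
  expect_true(all(or$nef$eig == 0))
})

test_that("unscattered transmission matches exp(-mu t) within 3 binomial sigma", {
  mono <- mono_spectrum(2)
  b <- beam_geometry(4, mono)
  p <- fixture_slab(1)
  n <- 1e5
  th <- transport_history(b, p, seed = 31, n_histories = n)
  # order-0 plane crossings
  transmitted <- sum(!is.na(th$history[, "exit_order"]) &
                       th$history[, "exit_order"] == 0)
  mu <- linear_attenuation("water", 1.0, 2)$total
  pexp <- exp(-20 * mu)
  se <- sqrt(pexp * (1 - pexp) / n)
  expect_lt(abs(transmitted / n - pexp), 3 * se)
})

test_that("energy is conserved per history to 1e-9 relative", {
  g <- shared_geometry()
  th <- transport_history(g$beam, g$phantom, seed = 77, n_histories = 2000)
  expect_lt(th$max_history_relerr, 1e-9)
  balance <- th$history[, "plane"] + th$history[, "absorbed"] +
    th$history[, "escaped"]
  expect_equal(balance, th$history[, "E0"], tolerance = 1e-9)
})

test_that("phase-space extraction is reproducible and scales with histories", {
  g <- shared_geometry()
  r1 <- run_phase_space_extraction(g$beam, g$phantom, 3000, seed = 2)
  r2 <- run_phase_space_extraction(g$beam, g$phantom, 3000, seed = 2)
  expect_identical(unclass(r1)[, ], unclass(r2)[, ])  # bit-exact
  r0 <- run_phase_space_extraction(g$beam, g$phantom, 0, seed = 2)
  expect_equal(nrow(r0), 0L)
  r4 <- run_phase_space_extraction(g$beam, g$phantom, 12000, seed = 2)
  ratio <- nrow(r4) / nrow(r1)
  expect_gt(ratio, 3); expect_lt(ratio, 5)  # ~linear growth
  # all records carry outgoing order >= 2 and unit direction vectors
  expect_true(all(r4[, "order"] >= 2))
  expect_equal(sqrt(rowSums(r4[, c("ux", "uy", "uz")]^2)),
               rep(1, nrow(r4)), tolerance = 1e-9)
})

test_that("central-axis primary fluence matches the analytic prediction", {
  mono <- mono_spectrum(2)
  b <- beam_geometry(10, mono)
  p <- fixture_slab(1)
  pl <- fixture_plane()
  or <- run_full_mc_oracle(b, p, pl, 4e5, seed = 13)
  mu <- linear_attenuation("water", 1.0, 2)$total
  inc <- incident_energy_fluence(b)
  mid <- (pl$n_pixels + 1) %/% 2
  pred <- 2 * exp(-20 * mu) / (4 * pi * 140^2) / inc
  got <- or$nef$primary[mid, mid]
  sig <- or$rel_sigma$primary[mid, mid] * got
  expect_lt(abs(got - pred), 3 * sig + 0.01 * pred)
})

test_that("category images partition the total plane energy exactly", {
  g <- shared_geometry()
  pl <- imaging_plane(extent = 300, pixel_size = 10, sid = 140)  # capture all
  or <- run_full_mc_oracle(g$beam, g$phantom, pl, 2e4, seed = 21)
  tallied <- (sum(or$nef$primary) + sum(or$nef$single) +
                sum(or$nef$multiple) + sum(or$nef$eig)) *
    or$incident_energy_fluence * pl$pixel_size^2 * or$n_histories /
    (or$solid_angle / (4 * pi))
  expect_equal(tallied, or$energy_ledger[["plane"]], tolerance = 1e-9)
  expect_equal(or$nef$total, or$nef$primary + or$nef$scatter)
})

test_that("doubling histories halves the per-pixel variance within batch noise", {
  g <- shared_geometry()
  or1 <- run_full_mc_oracle(g$beam, g$phantom, g$plane, 2e5, seed = 3)
  or2 <- run_full_mc_oracle(g$beam, g$phantom, g$plane, 8e5, seed = 3)
  mid <- 6:16
  ratio <- median((or1$rel_sigma$scatter[mid, mid] /
                     or2$rel_sigma$scatter[mid, mid])^2, na.rm = TRUE)
  expect_gt(ratio, 2.5); expect_lt(ratio, 6.5)  # expect ~4
})

test_that("record counts decay ~exponentially with scatter order", {
  g <- shared_geometry()
  rec <- run_phase_space_extraction(g$beam, g$phantom, 20000, seed = 2)
  oh <- attr(rec, "order_histogram")
  counts <- oh[oh > 0]
  expect_true(all(diff(counts[-(1:2)]) < 0))  # monotone decay beyond order 3
  lr <- log(counts[3:10])
  fit <- lm(lr ~ seq_along(lr))
  expect_lt(coef(fit)[2], -0.1)               # clear exponential falloff
  expect_gt(summary(fit)$r.squared, 0.98)
})
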