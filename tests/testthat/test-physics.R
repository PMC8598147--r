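# Klein-Nishina cross sections, Compton kinematics, attenuation tables and
# spectrum handling.

test_that("Klein-Nishina forward limit equals r_e^2 independent of energy", {
  for (E in c(0.1, 1, 6, 18)) {
    expect_equal(kn_differential_cross_section(E, 0), re2, tolerance = 1e-12)
  }
})

test_that("low-energy integrated cross section recovers the Thomson value", {
  sigma <- kn_total_quadrature(1e-4)
  expect_equal(sigma / 1e-24, 0.6652, tolerance = 2e-3)  # barn
  # closed form agrees with quadrature at all energies
  for (E in c(0.1, 0.511, 2, 18)) {
    expect_equal(kn_total_cross_section(E), kn_total_quadrature(E),
                 tolerance = 1e-6)
  }
})

test_that("differential cross section matches direct evaluation at 0.511 MeV, 90 degrees", {
  # at E = m_e c^2 and 90 degrees, E'/E = 1/2 and
  # dsigma/dOmega = (r_e^2/2)(1/4)(1/2 + 2 - 1) = 0.1875 r_e^2
  expect_equal(kn_differential_cross_section(mec2, pi / 2), 0.1875 * re2,
               tolerance = 1e-12)
  r <- 1 / (1 + (0.511 / mec2))
  expect_equal(kn_differential_cross_section(0.511, pi / 2),
               (re2 / 2) * r^2 * (r + 1 / r - 1), tolerance = 1e-12)
})

test_that("invalid energies are rejected", {
  expect_error(kn_differential_cross_section(-1, 0), "invalid-energy")
  expect_error(kn_differential_cross_section(NaN, 0), "invalid-energy")
  expect_error(compton_scattered_energy(0, 0), "invalid-energy")
})

test_that("Compton kinematics closed forms and monotonicity", {
  expect_equal(compton_scattered_energy(3.21, 0), 3.21)
  expect_equal(compton_scattered_energy(0.511, pi / 2), 0.2555, tolerance = 1e-3)
  expect_equal(compton_scattered_energy(100, pi), 0.2549, tolerance = 1e-3)
  th <- seq(0, pi, length.out = 50)
  for (E in c(0.3, 2, 18)) {
    ep <- compton_scattered_energy(E, th)
    expect_true(all(diff(ep) < 0))
    expect_true(all(ep > 0 & ep <= E))
  }
})

test_that("integrated KN cross section decreases with energy", {
  E <- exp(seq(log(0.05), log(20), length.out = 40))
  expect_true(all(diff(kn_total_cross_section(E)) < 0))
})

test_that("attenuation partial coefficients sum to the total", {
  for (m in materials()$name) {
    tab <- attenuation_tables()[[m]]
    expect_equal(tab$mu_over_rho_total,
                 tab$mu_over_rho_compton + tab$mu_over_rho_photoelectric +
                   tab$mu_over_rho_pair)
    expect_true(all(tab[, -1] >= 0))
    # Compton monotone decreasing above 0.5 MeV
    above <- tab$energy_MeV > 0.5
    expect_true(all(diff(tab$mu_over_rho_compton[above]) < 0))
  }
  E <- c(0.07, 0.9, 3.3, 15)
  la <- linear_attenuation("water", 1.0, E)
  expect_equal(la$total, la$compton + la$photoelectric + la$pair)
})

test_that("linear attenuation: zero density, node identity, log-log midpoint", {
  la0 <- linear_attenuation("cortical_bone", 0, c(0.1, 1, 10))
  expect_true(all(la0$total == 0))
  tab <- attenuation_tables()$water
  iE <- 12
  la <- linear_attenuation("water", 1.0, tab$energy_MeV[iE])
  expect_equal(la$total, tab$mu_over_rho_total[iE], tolerance = 1e-12)
  # hand log-log interpolation at the mid-log energy between two nodes
  e_mid <- exp((log(tab$energy_MeV[5]) + log(tab$energy_MeV[6])) / 2)
  expected <- exp((log(tab$mu_over_rho_compton[5]) +
                     log(tab$mu_over_rho_compton[6])) / 2)
  expect_equal(linear_attenuation("water", 1.0, e_mid)$compton, expected,
               tolerance = 1e-12)
  expect_error(linear_attenuation("water", 1.0, 25), "out-of-range")
  expect_error(linear_attenuation("water", 1.0, 0.01), "out-of-range")
})

test_that("pair production is zero below threshold and grows above", {
  la <- linear_attenuation("water", 1.0, c(0.5, 1.0, 2, 6, 18))
  expect_equal(la$pair[1:2], c(0, 0))
  expect_true(all(diff(la$pair[3:5]) > 0))
})

test_that("spectrum construction validates invariants", {
  s <- beam_spectrum("6MV")
  expect_equal(sum(s$bin_weights), 1, tolerance = 1e-12)
  n <- length(s$bin_weights)
  expect_true(all(s$representative_energy >= s$bin_edges[-(n + 1)] &
                    s$representative_energy <= s$bin_edges[-1]))
  expect_error(energy_spectrum(c(1, 2, 2), c(0.5, 0.5), c(1.5, 2)),
               "strictly increasing")
  expect_error(energy_spectrum(c(1, 2, 3), c(0.5, 0.5), c(2.5, 2.5)),
               "inside their bins")
})

test_that("rebinning merges weights, preserves total weight and mean energy", {
  s <- beam_spectrum("6MV")
  expect_equal(rebin_spectrum(s, 0.25)$bin_weights, s$bin_weights)
  r <- rebin_spectrum(s, 1)
  expect_equal(sum(r$bin_weights), 1, tolerance = 1e-12)
  # fluence-weighted representatives preserve the mean exactly; the paper's
  # requirement is < 2%
  brute_fine <- sum(s$bin_weights * s$representative_energy)
  brute_coarse <- sum(r$bin_weights * r$representative_energy)
  expect_equal(brute_coarse, brute_fine, tolerance = 1e-12)
  expect_lt(abs(brute_coarse - brute_fine) / brute_fine, 0.02)
  # two equal-weight bins at 1 and 3 MeV merge to representative energy 2
  s2 <- energy_spectrum(c(0.5, 1.5, 3.5), c(0.5, 0.5), c(1, 3))
  r2 <- rebin_spectrum(s2, 3)
  expect_equal(length(r2$bin_weights), 1L)
  expect_equal(r2$representative_energy, 2)
  expect_error(rebin_spectrum(s, 0.1), "invalid-rebin")
})

test_that("KN angular sampling reproduces quadrature moments", {
  for (E in c(0.511, 2, 6)) {
    th <- seq(-1, 1, length.out = 20001)
    r <- 1 / (1 + (E / mec2) * (1 - th))
    f <- r^2 * (r + 1 / r - (1 - th^2))
    norm <- sum((f[-1] + f[-length(f)]) / 2 * diff(th))
    m1 <- sum(((f * th)[-1] + (f * th)[-length(th)]) / 2 * diff(th)) / norm
    s <- epidscatter:::cpp_kahn_sample(E, 100000L, 4242L)
    se <- sd(s) / sqrt(length(s))
    expect_lt(abs(mean(s) - m1), 4 * se)
  }
})

test_that("spectrum and attenuation CSV round-trips", {
  f <- tempfile(fileext = ".csv")
  s <- beam_spectrum("18MV", bin_size = 0.5)
  write_spectrum_csv(s, f)
  s2 <- read_spectrum_csv(f)
  expect_equal(s2$bin_edges, s$bin_edges)
  expect_equal(s2$bin_weights, s$bin_weights, tolerance = 1e-12)
  expect_equal(s2$representative_energy, s$representative_energy,
               tolerance = 1e-12)
  f2 <- tempfile(fileext = ".csv")
  write_attenuation_csv("water", "mu_over_rho_compton", f2)
  df <- read.csv(f2)
  expect_equal(names(df), c("energy_MeV", "value"))
  expect_equal(df$value, attenuation_tables()$water$mu_over_rho_compton,
               tolerance = 1e-12)
})
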