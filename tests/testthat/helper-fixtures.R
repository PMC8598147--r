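# Shared fixtures and a lazy cache for the expensive validation runs, so
# the oracle comparisons are computed once per test session.

re2 <- 2.8179403262e-13^2
mec2 <- 0.51099895

fixture_spectrum_6mv <- function() beam_spectrum("6MV")

fixture_slab <- function(voxel_size = 1) build_water_slab(20, 40, voxel_size)

fixture_beam <- function(field = 10, spectrum = fixture_spectrum_6mv()) {
  beam_geometry(field, spectrum)
}

fixture_plane <- function() imaging_plane(extent = 42, pixel_size = 2, sid = 140)

# monoenergetic spectrum helper (narrow bin around E)
mono_spectrum <- function(E, halfwidth = 1e-3) {
  energy_spectrum(c(E - halfwidth, E + halfwidth), 1, E)
}

# Riemann-sum reference for radiological paths: subdivide the segment into
# n steps and accumulate density at midpoints (independent of the Siddon
# traversal under test).
riemann_rho_l <- function(p0, p1, phantom, n = 1e5) {
  d <- dim(phantom$density)
  h <- phantom$voxel_size
  t <- (seq_len(n) - 0.5) / n
  pts <- cbind(p0[1] + t * (p1[1] - p0[1]),
               p0[2] + t * (p1[2] - p0[2]),
               p0[3] + t * (p1[3] - p0[3]))
  dl <- sqrt(sum((p1 - p0)^2)) / n
  ix <- floor((pts[, 1] - phantom$origin[1]) / h) + 1
  iy <- floor((pts[, 2] - phantom$origin[2]) / h) + 1
  iz <- floor((pts[, 3] - phantom$origin[3]) / h) + 1
  ok <- ix >= 1 & ix <= d[1] & iy >= 1 & iy <= d[2] & iz >= 1 & iz <= d[3]
  sum(phantom$density[cbind(ix[ok], iy[ok], iz[ok])]) * dl
}

# numerical quadrature of the Klein-Nishina differential cross section
kn_total_quadrature <- function(E, n = 20001) {
  th <- seq(0, pi, length.out = n)
  f <- kn_differential_cross_section(E, th) * 2 * pi * sin(th)
  sum((f[-1] + f[-n]) / 2 * diff(th))
}

# ---------------------------------------------------------------------------
# Session cache for the scaled-down validation study shared by the
# acceptance tests: 20-cm water slab, 6 MV-like beam, 10x10 cm^2 field,
# 21x21 plane of 2-cm pixels.

.cache <- new.env(parent = emptyenv())

shared_geometry <- function() {
  if (is.null(.cache$geom)) {
    .cache$geom <- list(spectrum = fixture_spectrum_6mv(),
                        phantom = fixture_slab(1),
                        phantom_fine = build_water_slab(20, 40, 0.5),
                        beam = fixture_beam(10),
                        plane = fixture_plane())
  }
  .cache$geom
}

shared_oracle <- function() {
  if (is.null(.cache$oracle)) {
    g <- shared_geometry()
    .cache$oracle <- run_full_mc_oracle(g$beam, g$phantom, g$plane,
                                        n_histories = 1e8, seed = 11)
  }
  .cache$oracle
}

shared_th <- function() {
  if (is.null(.cache$th)) {
    g <- shared_geometry()
    lib <- build_kernel_library(g$spectrum, n_histories = 3e5, seed = 1101,
                                thicknesses = c(10, 20, 30),
                                air_gaps = c(20, 30, 40))
    .cache$th <- compute_total_th(g$phantom, g$beam, g$plane,
                                  settings = list(seed = 1,
                                                  kernel_library = lib))
  }
  .cache$th
}
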