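# Photon interaction physics shared by the tri-hybrid estimators and the MC
# oracle: Klein-Nishina cross sections, Compton kinematics, material data,
# mass attenuation tables and polyenergetic beam spectra.

# Physical constants (CODATA); lengths in cm, energies in MeV.
.re_cm <- 2.8179403262e-13          # classical electron radius
.mec2 <- 0.51099895                  # electron rest energy, MeV
.avogadro <- 6.02214076e23

.pkg_env <- new.env(parent = emptyenv())

#' Material inventory
#'
#' The five materials used by the procedural phantoms: water, air, lung,
#' soft tissue and cortical bone, with their default mass densities and
#' electron densities.  Electron density per gram is N_A * Z/A.
#'
#' @return A data.frame with columns `name`, `mass_density_default` (g/cm^3),
#'   `z_over_a`, and `electron_density_per_gram` (electrons/g).
#' @export
materials <- function() {
  df <- data.frame(
    name = c("water", "air", "lung", "soft_tissue", "cortical_bone"),
    mass_density_default = c(1.0, 0.0012, 0.26, 1.0, 1.85),
    z_over_a = c(0.55509, 0.49919, 0.55048, 0.55000, 0.51478),
    stringsAsFactors = FALSE
  )
  df$electron_density_per_gram <- .avogadro * df$z_over_a
  df
}

.material_index <- function(name) {
  m <- match(name, materials()$name)
  if (anyNA(m)) stop("unknown material: ", paste(name[is.na(m)], collapse = ", "))
  m
}

#' Klein-Nishina differential cross section
#'
#' Differential cross section per electron for Compton scattering of a photon
#' of energy `E` through polar angle `theta`,
#' \deqn{d\sigma/d\Omega = (r_e^2/2) (E'/E)^2 (E'/E + E/E' - \sin^2\theta),}
#' with `E'` the Compton-scattered energy.
#'
#' @param E Photon energy in MeV (positive, finite).
#' @param theta Scattering angle in radians, in `[0, pi]`.
#' @return Cross section in cm^2/sr per electron.
#' @export
kn_differential_cross_section <- function(E, theta) {
  if (any(!is.finite(E)) || any(E <= 0)) stop("invalid-energy: E must be finite and > 0")
  r <- 1 / (1 + (E / .mec2) * (1 - cos(theta)))   # E'/E
  (.re_cm^2 / 2) * r^2 * (r + 1 / r - sin(theta)^2)
}

#' Total Klein-Nishina cross section
#'
#' Closed-form integral of the Klein-Nishina differential cross section over
#' all solid angle, per electron.
#'
#' @param E Photon energy in MeV.
#' @return Cross section in cm^2 per electron.
#' @export
kn_total_cross_section <- function(E) {
  if (any(!is.finite(E)) || any(E <= 0)) stop("invalid-energy: E must be finite and > 0")
  k <- E / .mec2
  2 * pi * .re_cm^2 * (
    (1 + k) / k^2 * (2 * (1 + k) / (1 + 2 * k) - log(1 + 2 * k) / k) +
      log(1 + 2 * k) / (2 * k) - (1 + 3 * k) / (1 + 2 * k)^2
  )
}

#' Compton-scattered photon energy
#'
#' Compton kinematics for a free electron at rest:
#' `E' = E / (1 + (E/m_e c^2)(1 - cos theta))`.
#'
#' @inheritParams kn_differential_cross_section
#' @return Scattered photon energy in MeV, `0 < E' <= E`.
#' @export
compton_scattered_energy <- function(E, theta) {
  if (any(!is.finite(E)) || any(E <= 0)) stop("invalid-energy: E must be finite and > 0")
  E / (1 + (E / .mec2) * (1 - cos(theta)))
}

# ---------------------------------------------------------------------------
# Mass attenuation tables
#
# The Compton column is computed exactly from the Klein-Nishina total cross
# section times the material electron density, which makes the analytic
# estimators and the Monte Carlo engine share identical Compton physics by
# construction.  The photoelectric and pair-production columns are compact
# smooth parametrizations with magnitudes representative of light tissues and
# bone at megavoltage energies; they are used self-consistently everywhere in
# the package (estimators and oracle see the same tables).

.photo_coeff_50kev <- c(water = 2.2e-3, air = 2.4e-3, lung = 2.2e-3,
                        soft_tissue = 2.2e-3, cortical_bone = 2.2e-2)
.pair_scale <- c(water = 3.08e-3, air = 3.08e-3, lung = 3.05e-3,
                 soft_tissue = 3.03e-3, cortical_bone = 4.4e-3)
.pair_threshold <- 2 * .mec2  # 1.022 MeV

.pair_shape <- function(E) {
  f <- rep(0, length(E))
  above <- E > .pair_threshold
  f[above] <- (1 - .pair_threshold / E[above])^3 * log(1 + E[above] / .pair_threshold)
  f
}

#' Mass attenuation tables for all package materials
#'
#' One table per material on a common 30-point log-spaced energy grid
#' covering 0.05-20 MeV, partitioned into Compton (incoherent),
#' photoelectric and pair-production mass attenuation coefficients.
#' Coefficients are interpolated log-log between grid points (linearly where
#' a coefficient is zero at a bracketing node, as below the pair threshold).
#'
#' @return A named list of data.frames with columns `energy_MeV`,
#'   `mu_over_rho_compton`, `mu_over_rho_photoelectric`, `mu_over_rho_pair`
#'   and `mu_over_rho_total` (all cm^2/g).
#' @export
attenuation_tables <- function() {
  if (!is.null(.pkg_env$atten_tables)) return(.pkg_env$atten_tables)
  mats <- materials()
  E <- exp(seq(log(0.05), log(20), length.out = 30))
  tabs <- lapply(seq_len(nrow(mats)), function(i) {
    nm <- mats$name[i]
    compton <- mats$electron_density_per_gram[i] * kn_total_cross_section(E)
    photo <- .photo_coeff_50kev[[nm]] * (E / 0.05)^(-3)
    pair <- .pair_scale[[nm]] * .pair_shape(E)
    data.frame(
      energy_MeV = E,
      mu_over_rho_compton = compton,
      mu_over_rho_photoelectric = photo,
      mu_over_rho_pair = pair,
      mu_over_rho_total = compton + photo + pair
    )
  })
  names(tabs) <- mats$name
  .pkg_env$atten_tables <- tabs
  tabs
}

# Interpolate one coefficient column at energies E (log-log; linear fallback
# when a bracketing node is zero).  No extrapolation.
.interp_coeff <- function(tab, column, E) {
  x <- tab$energy_MeV
  if (any(E < x[1] - 1e-12) || any(E > x[length(x)] + 1e-12))
    stop("out-of-range: energy outside attenuation table range [",
         signif(x[1], 4), ", ", signif(x[length(x)], 4), "] MeV")
  E <- pmin(pmax(E, x[1]), x[length(x)])
  y <- tab[[column]]
  i <- findInterval(E, x, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(x) - 1L)
  y0 <- y[i]; y1 <- y[i + 1L]
  out <- numeric(length(E))
  loglog <- y0 > 0 & y1 > 0
  t_log <- (log(E) - log(x[i])) / (log(x[i + 1L]) - log(x[i]))
  out[loglog] <- exp(log(y0[loglog]) + t_log[loglog] * (log(y1[loglog]) - log(y0[loglog])))
  lin <- !loglog
  if (any(lin)) {
    t_lin <- (E[lin] - x[i][lin]) / (x[i + 1L][lin] - x[i][lin])
    out[lin] <- y0[lin] + t_lin * (y1[lin] - y0[lin])
  }
  if (column == "mu_over_rho_pair") out[E < .pair_threshold] <- 0
  out
}

#' Linear attenuation coefficients, partitioned by process
#'
#' @param material Material name (see [materials()]).
#' @param density Mass density in g/cm^3 (>= 0).
#' @param E Photon energies in MeV, within the table range (no extrapolation).
#' @return A data.frame with columns `energy_MeV`, `compton`,
#'   `photoelectric`, `pair` and `total` linear attenuation coefficients
#'   (cm^-1).
#' @export
linear_attenuation <- function(material, density, E) {
  stopifnot(length(material) == 1L, length(density) == 1L)
  if (density < 0) stop("density must be >= 0")
  tab <- attenuation_tables()[[materials()$name[.material_index(material)]]]
  comp <- .interp_coeff(tab, "mu_over_rho_compton", E) * density
  photo <- .interp_coeff(tab, "mu_over_rho_photoelectric", E) * density
  pair <- .interp_coeff(tab, "mu_over_rho_pair", E) * density
  data.frame(energy_MeV = E, compton = comp, photoelectric = photo,
             pair = pair, total = comp + photo + pair)
}

# ---------------------------------------------------------------------------
# Polyenergetic beam spectra

#' Construct an energy spectrum
#'
#' @param bin_edges Increasing vector of bin edges in MeV.
#' @param bin_weights Relative fluence fraction per bin (normalized to 1).
#' @param representative_energy Fluence-weighted mean energy of each bin, MeV.
#' @return An object of class `energy_spectrum`.
#' @export
energy_spectrum <- function(bin_edges, bin_weights, representative_energy) {
  n <- length(bin_weights)
  stopifnot(length(bin_edges) == n + 1L, length(representative_energy) == n)
  if (any(diff(bin_edges) <= 0)) stop("bin_edges must be strictly increasing")
  if (any(bin_weights < 0)) stop("bin_weights must be >= 0")
  s <- sum(bin_weights)
  if (s <= 0) stop("spectrum has zero total weight")
  w <- bin_weights / s
  inside <- representative_energy >= bin_edges[-(n + 1L)] - 1e-12 &
    representative_energy <= bin_edges[-1L] + 1e-12
  if (!all(inside)) stop("representative energies must lie inside their bins")
  structure(list(bin_edges = bin_edges, bin_weights = w,
                 representative_energy = representative_energy),
            class = "energy_spectrum")
}

#' @export
print.energy_spectrum <- function(x, ...) {
  cat(sprintf("<energy_spectrum> %d bins, %.3g-%.3g MeV, mean %.4g MeV\n",
              length(x$bin_weights), x$bin_edges[1],
              x$bin_edges[length(x$bin_edges)], spectrum_mean_energy(x)))
  invisible(x)
}

#' Mean energy of a spectrum
#'
#' Fluence-weighted mean of the representative bin energies.
#'
#' @param spectrum An [energy_spectrum()].
#' @return Mean energy in MeV.
#' @export
spectrum_mean_energy <- function(spectrum) {
  sum(spectrum$bin_weights * spectrum$representative_energy)
}

# Relative fluence density of the parametric linac-like spectra: a gamma-type
# shape E^2 exp(-2E/E_mode) with mode near one third of the nominal
# accelerating potential and an exponential-like tail cut at the nominal
# energy.  Support starts at 0.25 MeV, above the transport cutoff.
.spectrum_density <- function(E, nominal_MeV) {
  mode <- nominal_MeV / 3
  ifelse(E < 0.25 | E > nominal_MeV, 0, E^2 * exp(-2 * E / mode))
}

#' Parametric 6 MV-like and 18 MV-like beam spectra
#'
#' Deterministic polyenergetic fixture spectra binned on a native grid.
#' Bin weights are integrals of a gamma-type fluence density (mode near one
#' third of the nominal energy, tail to the nominal energy); representative
#' energies are fluence-weighted in-bin means, so rebinning preserves the
#' spectrum mean energy.
#'
#' @param nominal `"6MV"` or `"18MV"`.
#' @param bin_size Native bin width in MeV (default 0.25).
#' @return An [energy_spectrum()].
#' @export
beam_spectrum <- function(nominal = c("6MV", "18MV"), bin_size = 0.25) {
  nominal <- match.arg(nominal)
  e_max <- if (nominal == "6MV") 6 else 18
  edges <- seq(0.25, e_max, by = bin_size)
  if (abs(edges[length(edges)] - e_max) > 1e-9) edges <- c(edges, e_max)
  nb <- length(edges) - 1L
  w <- numeric(nb); rep_e <- numeric(nb)
  for (b in seq_len(nb)) {
    eg <- seq(edges[b], edges[b + 1L], length.out = 101L)
    f <- .spectrum_density(eg, e_max)
    w[b] <- sum((f[-1] + f[-length(f)]) / 2 * diff(eg))
    num <- sum((f[-1] * eg[-1] + f[-length(f)] * eg[-length(eg)]) / 2 * diff(eg))
    rep_e[b] <- if (w[b] > 0) num / w[b] else mean(eg)
  }
  energy_spectrum(edges, w, rep_e)
}

#' Rebin a spectrum to coarser bins
#'
#' Merges native bins into groups anchored at the first bin edge.  Weights of
#' merged bins are summed; the representative energy of a merged bin is the
#' fluence-weighted mean of its members, which preserves the spectrum mean
#' energy exactly.
#'
#' @param spectrum An [energy_spectrum()].
#' @param bin_size Target bin width in MeV; must be at least the source
#'   resolution.
#' @return An [energy_spectrum()].
#' @export
rebin_spectrum <- function(spectrum, bin_size) {
  if (bin_size <= 0) stop("bin_size must be > 0")
  widths <- diff(spectrum$bin_edges)
  if (bin_size < max(widths) - 1e-12)
    stop("invalid-rebin: bin_size smaller than the source resolution")
  e0 <- spectrum$bin_edges[1]
  grp <- floor((spectrum$bin_edges[-length(spectrum$bin_edges)] - e0) / bin_size + 1e-9)
  ug <- sort(unique(grp))
  w <- vapply(ug, function(g) sum(spectrum$bin_weights[grp == g]), 0)
  rep_e <- vapply(ug, function(g) {
    wi <- spectrum$bin_weights[grp == g]
    ri <- spectrum$representative_energy[grp == g]
    if (sum(wi) > 0) sum(wi * ri) / sum(wi) else mean(range(ri))
  }, 0)
  lo <- vapply(ug, function(g) min(spectrum$bin_edges[-length(spectrum$bin_edges)][grp == g]), 0)
  hi <- vapply(ug, function(g) max(spectrum$bin_edges[-1][grp == g]), 0)
  if (any(abs(lo[-1] - hi[-length(hi)]) > 1e-9)) stop("invalid-rebin: non-contiguous groups")
  energy_spectrum(c(lo, hi[length(hi)]), w, rep_e)
}

# ---------------------------------------------------------------------------
# CSV serialization (dialect: header row, '.' decimal separator)

#' Write a spectrum to CSV
#'
#' Columns `energy_MeV` (representative bin energy) and `value` (bin weight);
#' bin edges are carried in `#`-prefixed comment lines so the spectrum can be
#' reconstructed exactly.
#'
#' @param spectrum An [energy_spectrum()].
#' @param path Output file path.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# bin_edges_MeV: ",
                    paste(format(spectrum$bin_edges, digits = 15), collapse = " ")), con)
  writeLines("energy_MeV,value", con)
  writeLines(paste(format(spectrum$representative_energy, digits = 15),
                   format(spectrum$bin_weights, digits = 15), sep = ","), con)
  invisible(path)
}

#' Read a spectrum written by [write_spectrum_csv()]
#'
#' @param path File path.
#' @return An [energy_spectrum()].
#' @export
read_spectrum_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# bin_edges_MeV:", lines, value = TRUE)
  edges <- as.numeric(strsplit(sub("^# bin_edges_MeV: *", "", hdr[1]), " +")[[1]])
  body <- read.csv(textConnection(lines[!startsWith(lines, "#")]))
  energy_spectrum(edges, body$value, body$energy_MeV)
}

#' Write one attenuation coefficient column to CSV
#'
#' @param material Material name.
#' @param column One of the `mu_over_rho_*` columns of [attenuation_tables()].
#' @param path Output file path.
#' @export
write_attenuation_csv <- function(material, column, path) {
  tab <- attenuation_tables()[[materials()$name[.material_index(material)]]]
  df <- data.frame(energy_MeV = tab$energy_MeV, value = tab[[column]])
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
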