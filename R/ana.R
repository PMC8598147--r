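# Analytical single-scatter estimator: deterministic integration over
# in-field voxels x energy bins x pixels using the Klein-Nishina cross
# section, Compton kinematics and exact ray tracing.

#' Normalized energy fluence image constructor
#'
#' @param values Pixel matrix of normalized energy fluence (dimensionless).
#' @param number_fluence Pixel matrix of number fluence on the same
#'   normalization (used for per-pixel mean energy).
#' @param component One of `"single"`, `"multiple"`, `"eig"`, `"total"`.
#' @param plane The [imaging_plane()] the image lives on.
#' @param sampling Named list of sampling metadata (voxel size, energy bin
#'   size, MC histories, order range, ...).
#' @return An object of class `nef_image`.
#' @export
nef_image <- function(values, number_fluence, component, plane,
                      sampling = list()) {
  stopifnot(is.matrix(values), all(dim(values) == plane$n_pixels))
  if (any(values < 0)) stop("NEF values must be >= 0")
  structure(list(values = values, number_fluence = number_fluence,
                 mean_energy = ifelse(number_fluence > 0,
                                      values / number_fluence, NA_real_),
                 component = component, plane = plane, sampling = sampling),
            class = "nef_image")
}

#' @export
print.nef_image <- function(x, ...) {
  cat(sprintf("<nef_image> %s component, %dx%d pixels, mean NEF %.4g\n",
              x$component, nrow(x$values), ncol(x$values), mean(x$values)))
  invisible(x)
}

#' Incident energy fluence entering the phantom
#'
#' Analytic central-axis energy fluence of the point source at the phantom
#' entrance plane, per isotropic source photon:
#' `sum_b w_b E_b / (4 pi SSD^2)`.  This is the normalization denominator
#' shared by every NEF component and by the MC oracle, so percent
#' differences between them are denominator-free.
#'
#' @param beam A [beam_geometry()].
#' @return Energy fluence in MeV/cm^2 per source photon.
#' @export
incident_energy_fluence <- function(beam) {
  spectrum_mean_energy(beam$spectrum) / (4 * pi * beam$ssd^2)
}

#' Analytical single-scatter NEF (the ANA method)
#'
#' For every in-field voxel (voxel-center test, closed field boundary),
#' energy bin and pixel, accumulates
#' `w_b exp(-tau_in)/(4 pi d_sv^2) * rho_e V dsigma/dOmega(E, theta) *
#' cos(alpha)/d_vp^2 * E' * exp(-tau_out)`,
#' then divides by the incident energy fluence entering the phantom.
#' Deterministic: identical inputs give bit-identical output.
#'
#' @param phantom A [voxel_phantom()].
#' @param beam A [beam_geometry()].
#' @param plane An [imaging_plane()].
#' @param voxel_size Integration voxel size in cm; the phantom is resampled
#'   to it first (must be commensurate).  `NULL` keeps the phantom grid.
#' @param energy_bin_size Spectrum bin size in MeV; the beam spectrum is
#'   rebinned to it (must be >= the native resolution).  `NULL` keeps the
#'   native binning.
#' @return A [nef_image()] with component `"single"`.
#' @export
compute_single_scatter_nef <- function(phantom, beam, plane,
                                       voxel_size = NULL,
                                       energy_bin_size = NULL) {
  if (!is.null(voxel_size)) phantom <- resample_phantom(phantom, voxel_size)
  if (!is.null(energy_bin_size))
    beam$spectrum <- rebin_spectrum(beam$spectrum, energy_bin_size)
  res <- cpp_ana_single(.grid_list(phantom), .xs_list(), .beam_list(beam),
                        .plane_list(plane))
  inc <- incident_energy_fluence(beam)
  nef_image(.as_plane_matrix(res$EF, plane) / inc,
            .as_plane_matrix(res$NF, plane) / inc,
            "single", plane,
            sampling = list(voxel_size = phantom$voxel_size,
                            energy_bin_size = energy_bin_size,
                            n_bins = length(beam$spectrum$bin_weights),
                            n_voxels = res$n_voxels))
}
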