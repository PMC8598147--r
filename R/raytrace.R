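# Exact ray tracing through the voxel grid: per-voxel chord lengths,
# optical depth and water-equivalent thickness.

#' Exact voxel traversal of a line segment
#'
#' Siddon-style parametric plane-crossing traversal: every voxel intersected
#' by the segment `p0 -> p1` appears exactly once with its exact chord
#' length.  Segments running exactly along voxel faces are nudged 1e-10 cm
#' into the grid interior; chords shorter than 1e-12 cm are dropped.
#'
#' @param p0,p1 Length-3 positions in cm (must differ).
#' @param phantom A [voxel_phantom()].
#' @return A list of class `radiological_path`:
#'   `traversed_voxel_indices` (matrix of 1-based `(i, j, k)` indices),
#'   `geometric_lengths` (cm), and `water_equivalent_thickness`
#'   (cm; the path integral of density over the in-grid chord divided by
#'   the density of water).
#' @export
siddon_trace <- function(p0, p1, phantom) {
  res <- cpp_siddon_trace(as.numeric(p0), as.numeric(p1), .grid_list(phantom))
  structure(list(traversed_voxel_indices = res$indices,
                 geometric_lengths = res$lengths,
                 water_equivalent_thickness = res$water_equivalent_thickness),
            class = "radiological_path")
}

#' Optical depth along a segment
#'
#' Line integral of the total linear attenuation coefficient at energy `E`
#' over the in-grid portion of the segment; the corresponding attenuation
#' factor is `exp(-optical_depth)`.
#'
#' @inheritParams siddon_trace
#' @param E Photon energy in MeV (within the attenuation table range).
#' @return Dimensionless optical depth (>= 0).
#' @export
optical_depth <- function(p0, p1, phantom, E) {
  if (E < 0.05 || E > 20)
    stop("out-of-range: energy outside attenuation table range")
  cpp_optical_depth(as.numeric(p0), as.numeric(p1), .grid_list(phantom),
                    .xs_list(), E)
}

#' Water-equivalent thickness along a segment
#'
#' @inheritParams siddon_trace
#' @return WET in cm: the density-weighted in-grid path length divided by
#'   the density of water (1 g/cm^3).
#' @export
water_equivalent_thickness <- function(p0, p1, phantom) {
  rl <- cpp_path_rho_l(as.numeric(p0), as.numeric(p1), .grid_list(phantom),
                       nrow(materials()))
  sum(rl) / 1.0
}
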