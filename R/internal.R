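# Internal adapters between R-level objects and the C++ core.

.grid_list <- function(phantom) {
  list(density = as.numeric(phantom$density),
       material_id = as.integer(phantom$material_id),
       dims = as.integer(dim(phantom$density)),
       origin = as.numeric(phantom$origin),
       voxel_size = as.numeric(phantom$voxel_size))
}

.xs_list <- function() {
  if (is.null(.pkg_env$xs_list)) {
    .pkg_env$xs_list <- list(tables = attenuation_tables(),
                             electron_density_per_gram = materials()$electron_density_per_gram)
  }
  .pkg_env$xs_list
}

.beam_list <- function(beam) {
  s <- beam$spectrum
  list(fx = beam$field_size_at_iso[1], fy = beam$field_size_at_iso[2],
       iso = beam$iso,
       bin_weights = s$bin_weights, bin_energies = s$representative_energy)
}

.plane_list <- function(plane) {
  list(z = plane$distance_from_source, half_extent = plane$extent / 2,
       pixel_size = plane$pixel_size, n_pixels = as.integer(plane$n_pixels))
}

.as_plane_matrix <- function(v, plane) {
  matrix(v, nrow = plane$n_pixels, ncol = plane$n_pixels)
}

.check_seed <- function(seed) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("missing-seed: all stochastic entry points require an explicit seed")
  as.integer(seed)
}
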