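# Pencil-beam scatter kernels for the electron-interaction-generated (EIG)
# component: kernel generation by Monte Carlo on water slabs, a
# (water-equivalent thickness x air gap) library with bilinear
# interpolation, and convolution/superposition over the incident fluence.

#' Generate one EIG pencil-beam scatter kernel
#'
#' Transports a parallel pencil beam through a water slab of the given
#' thickness and scores the EIG (positron-annihilation-originated) energy
#' fluence on a plane `air_gap` cm below the exit surface, on a 0.5 cm
#' kernel grid.  The kernel is normalized per unit incident pencil energy
#' and radially averaged (the generation geometry is cylindrically
#' symmetric, so the averaging suppresses MC noise without bias).
#'
#' @param thickness Water slab thickness, cm.
#' @param air_gap Exit-surface-to-plane distance, cm.
#' @param spectrum An [energy_spectrum()].
#' @param n_histories MC histories.
#' @param seed Explicit RNG seed (required).
#' @param extent Lateral kernel extent, cm (default 70; the annihilation halo is broad).
#' @param resolution Kernel grid resolution, cm (default 0.5).
#' @return An object of class `scatter_kernel` with fields `ef` and `nf`
#'   (kernel grids: EIG energy/number fluence per cm^2 per unit incident
#'   pencil energy), `thickness`, `air_gap`, `resolution`, `extent`,
#'   `n_histories`, `seed`.
#' @export
generate_kernel <- function(thickness, air_gap, spectrum, n_histories, seed,
                            extent = 70, resolution = 0.5) {
  stopifnot(thickness > 0, air_gap > 0)
  seed <- .check_seed(seed)
  slab_lat <- 2 * ceiling(extent / 2) + 10
  phantom <- build_water_slab(thickness, lateral = slab_lat, voxel_size = 1,
                              ssd = 0)
  nk <- as.integer(round(extent / resolution))
  plane <- imaging_plane(extent = extent, pixel_size = resolution,
                         sid = thickness + air_gap)
  # dummy beam fields; the pencil source overrides the aperture sampling
  beam_l <- list(fx = 1, fy = 1, iso = 100,
                 bin_weights = spectrum$bin_weights,
                 bin_energies = spectrum$representative_energy)
  res <- cpp_mc_run(.grid_list(phantom), .xs_list(), beam_l,
                    .plane_list(plane), n_histories, seed,
                    .mc_opts(tally = TRUE, pencil = TRUE,
                             pencil_origin = c(0, 0, -1)))
  e_in <- res$energy_ledger[["initial"]]
  ef <- .as_plane_matrix(res$EF[, 4], plane) / resolution^2 / e_in
  nf <- .as_plane_matrix(res$NF[, 4], plane) / resolution^2 / e_in
  structure(list(ef = .radial_average(ef, resolution),
                 nf = .radial_average(nf, resolution),
                 thickness = thickness, air_gap = air_gap,
                 resolution = resolution, extent = extent, n_pixels = nk,
                 n_histories = n_histories, seed = seed),
            class = "scatter_kernel")
}

# Average a centered kernel grid over radial bins of one grid spacing.
.radial_average <- function(m, resolution) {
  n <- nrow(m)
  cx <- (seq_len(n) - 0.5 - n / 2) * resolution
  r <- sqrt(outer(cx^2, cx^2, "+"))
  bin <- floor(r / resolution)
  means <- tapply(as.vector(m), as.vector(bin), mean)
  matrix(means[as.character(as.vector(bin))], n, n)
}

#' Build a pencil-beam scatter-kernel library
#'
#' @param thicknesses Strictly increasing water-equivalent thickness nodes,
#'   cm (default `c(5, 10, 20, 30, 40)`).
#' @param air_gaps Strictly increasing air-gap nodes, cm (default
#'   `c(10, 20, 30, 40, 50)`).
#' @param spectrum An [energy_spectrum()].
#' @param n_histories MC histories per kernel.
#' @param seed Base seed; kernel `(i, j)` uses `seed + (i-1)*length(air_gaps) + j`.
#' @inheritParams generate_kernel
#' @return An object of class `scatter_kernel_library`.
#' @export
build_kernel_library <- function(spectrum, n_histories, seed,
                                 thicknesses = c(5, 10, 20, 30, 40),
                                 air_gaps = c(10, 20, 30, 40, 50),
                                 extent = 70, resolution = 0.5) {
  seed <- .check_seed(seed)
  if (any(diff(thicknesses) <= 0) || any(diff(air_gaps) <= 0))
    stop("node grids must be strictly increasing")
  kernels <- vector("list", length(thicknesses) * length(air_gaps))
  dim(kernels) <- c(length(thicknesses), length(air_gaps))
  for (i in seq_along(thicknesses))
    for (j in seq_along(air_gaps))
      kernels[[i, j]] <- generate_kernel(
        thicknesses[i], air_gaps[j], spectrum, n_histories,
        seed + (i - 1L) * length(air_gaps) + j,
        extent = extent, resolution = resolution)
  structure(list(thicknesses = thicknesses, air_gaps = air_gaps,
                 kernels = kernels, resolution = resolution,
                 extent = extent, n_histories = n_histories, seed = seed),
            class = "scatter_kernel_library")
}

#' @export
print.scatter_kernel_library <- function(x, ...) {
  cat(sprintf("<scatter_kernel_library> %d x %d nodes (thickness %s cm; gap %s cm)\n",
              length(x$thicknesses), length(x$air_gaps),
              paste(x$thicknesses, collapse = "/"),
              paste(x$air_gaps, collapse = "/")))
  invisible(x)
}

.hull_locate <- function(nodes, q) {
  i <- findInterval(q, nodes, rightmost.closed = TRUE)
  if (i < 1 || q > nodes[length(nodes)] + 1e-9)
    stop("extrapolation-refused: query outside the kernel node hull")
  min(i, length(nodes) - 1L)
}

#' Bilinear kernel interpolation
#'
#' Element-wise bilinear combination of the four node kernels surrounding
#' the query point.  Exact at nodes; refuses to extrapolate.
#'
#' @param lib A [build_kernel_library()].
#' @param thickness,air_gap Query point, cm (inside the node hull).
#' @return A `scatter_kernel`.
#' @export
interpolate_kernel <- function(lib, thickness, air_gap) {
  i <- .hull_locate(lib$thicknesses, thickness)
  j <- .hull_locate(lib$air_gaps, air_gap)
  tx <- (thickness - lib$thicknesses[i]) /
    (lib$thicknesses[i + 1] - lib$thicknesses[i])
  ty <- (air_gap - lib$air_gaps[j]) / (lib$air_gaps[j + 1] - lib$air_gaps[j])
  mix <- function(field) {
    (1 - tx) * (1 - ty) * lib$kernels[[i, j]][[field]] +
      tx * (1 - ty) * lib$kernels[[i + 1, j]][[field]] +
      (1 - tx) * ty * lib$kernels[[i, j + 1]][[field]] +
      tx * ty * lib$kernels[[i + 1, j + 1]][[field]]
  }
  k <- lib$kernels[[i, j]]
  k$ef <- mix("ef"); k$nf <- mix("nf")
  k$thickness <- thickness; k$air_gap <- air_gap
  k
}

#' EIG scatter NEF by convolution/superposition (the PBSK method)
#'
#' Samples the incident field into divergent pencils on a lattice at the
#' phantom entrance plane; for each pencil, computes the water-equivalent
#' thickness and exit air gap along its ray by exact ray tracing, selects
#' the kernel by bilinear interpolation, weights it by the pencil's incident
#' energy, and superposes it at the pencil's projected position on the
#' imaging plane.
#'
#' @param phantom A [voxel_phantom()].
#' @param beam A [beam_geometry()].
#' @param plane An [imaging_plane()].
#' @param lib A [build_kernel_library()].
#' @param sampling_resolution Pencil lattice spacing in cm (default 0.5).
#' @param coverage `"error"` (default) refuses queries outside the kernel
#'   node hull; `"clamp"` clamps them to the hull boundary (useful for
#'   heterogeneous phantoms where grazing rays have near-zero thickness and
#'   negligible EIG production).
#' @return A [nef_image()] with component `"eig"`.
#' @export
compute_eig_nef <- function(phantom, beam, plane, lib,
                            sampling_resolution = 0.5,
                            coverage = c("error", "clamp")) {
  coverage <- match.arg(coverage)
  z0 <- phantom$origin[3]
  pz <- plane$distance_from_source
  half_entrance <- max(beam$field_size_at_iso) / 2 * z0 / beam$iso +
    sampling_resolution
  nc <- ceiling(2 * half_entrance / sampling_resolution)
  cc <- (seq_len(nc) - 0.5 - nc / 2) * sampling_resolution
  cells <- expand.grid(x = cc, y = cc)
  keep <- in_field(cbind(cells$x, cells$y, z0), beam)
  cells <- cells[keep, , drop = FALSE]
  np <- plane$n_pixels
  EF <- matrix(0, np, np)
  NF <- matrix(0, np, np)
  if (nrow(cells) == 0) {
    return(nef_image(EF, NF, "eig", plane,
                     sampling = list(resolution = sampling_resolution)))
  }
  nk <- lib$kernels[[1, 1]]$n_pixels
  koff <- (seq_len(nk) - 0.5 - nk / 2) * lib$resolution
  kx <- rep(koff, times = nk); ky <- rep(koff, each = nk)
  acell <- sampling_resolution^2
  akc <- lib$resolution^2
  mean_e <- spectrum_mean_energy(beam$spectrum)
  gl <- .grid_list(phantom)
  nmat <- nrow(materials())
  zhi <- phantom$origin[3] + dim(phantom$density)[3] * phantom$voxel_size
  for (r in seq_len(nrow(cells))) {
    p_ent <- c(cells$x[r], cells$y[r], z0)
    d_ent <- sqrt(sum(p_ent^2))
    u <- p_ent / d_ent
    p_far <- u * (pz / u[3])
    wet <- sum(cpp_path_rho_l(c(0, 0, 0), p_far, gl, nmat))
    exit_t <- zhi / u[3]            # along-ray distance to the grid exit plane
    gap <- pz / u[3] - exit_t
    q_t <- wet; q_g <- gap
    if (coverage == "clamp") {
      q_t <- min(max(q_t, lib$thicknesses[1]), lib$thicknesses[length(lib$thicknesses)])
      q_g <- min(max(q_g, lib$air_gaps[1]), lib$air_gaps[length(lib$air_gaps)])
    }
    kern <- tryCatch(interpolate_kernel(lib, q_t, q_g), error = function(e)
      stop("library-coverage failure: ", conditionMessage(e)))
    # incident energy on the cell per isotropic source photon
    e_cell <- mean_e / (4 * pi * d_ent^2) * u[3] * acell
    proj <- p_ent[1:2] * (pz / z0)
    pxi <- floor((kx + proj[1] + plane$extent / 2) / plane$pixel_size) + 1
    pyi <- floor((ky + proj[2] + plane$extent / 2) / plane$pixel_size) + 1
    ok <- pxi >= 1 & pxi <= np & pyi >= 1 & pyi <= np
    if (!any(ok)) next
    idx <- cbind(pxi[ok], pyi[ok])
    add_ef <- as.vector(kern$ef)[ok] * akc * e_cell / plane$pixel_size^2
    add_nf <- as.vector(kern$nf)[ok] * akc * e_cell / plane$pixel_size^2
    agg_e <- rowsum(add_ef, group = (idx[, 1] - 1L) * np + (idx[, 2] - 1L))
    agg_n <- rowsum(add_nf, group = (idx[, 1] - 1L) * np + (idx[, 2] - 1L))
    g <- as.integer(rownames(agg_e))
    gi <- g %/% np + 1L; gj <- g %% np + 1L
    EF[cbind(gi, gj)] <- EF[cbind(gi, gj)] + agg_e[, 1]
    NF[cbind(gi, gj)] <- NF[cbind(gi, gj)] + agg_n[, 1]
  }
  inc <- incident_energy_fluence(beam)
  nef_image(EF / inc, NF / inc, "eig", plane,
            sampling = list(resolution = sampling_resolution,
                            n_pencils = nrow(cells)))
}
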