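# Voxel phantoms, beam geometry and the imaging plane.
#
# Coordinate system: right-handed, origin at the point source, central axis
# +z toward the imager.  All positions in cm.  Voxel indices are 1-based on
# the R side (0-based internally); voxel ownership is half-open
# [lower, upper).  Grid arrays are ordered x fastest, z slowest.

#' Construct a voxel phantom
#'
#' @param density 3D array of mass density (g/cm^3), dims `(nx, ny, nz)`.
#' @param material 3D array of material names (see [materials()]) congruent
#'   with `density`, or a single name recycled to the grid.
#' @param voxel_size Isotropic voxel edge length in cm.
#' @param origin Coordinates (cm) of the grid corner with the smallest
#'   x, y, z (room frame, source at the origin).
#' @return An object of class `voxel_phantom`.
#' @export
voxel_phantom <- function(density, material, voxel_size, origin) {
  stopifnot(length(dim(density)) == 3L, voxel_size > 0, length(origin) == 3L)
  if (any(density < 0)) stop("density must be >= 0 everywhere")
  if (length(material) == 1L) material <- array(material, dim = dim(density))
  if (!identical(dim(material), dim(density)))
    stop("density and material grids must be congruent")
  mat_id <- array(.material_index(as.vector(material)), dim = dim(density))
  structure(list(density = density, material_id = mat_id,
                 voxel_size = voxel_size, origin = as.numeric(origin)),
            class = "voxel_phantom")
}

#' @export
print.voxel_phantom <- function(x, ...) {
  d <- dim(x$density)
  cat(sprintf("<voxel_phantom> %dx%dx%d voxels of %.3g cm, mass %.4g g\n",
              d[1], d[2], d[3], x$voxel_size, phantom_mass(x)))
  invisible(x)
}

#' Total phantom mass
#'
#' @param phantom A [voxel_phantom()].
#' @return Mass in grams.
#' @export
phantom_mass <- function(phantom) {
  sum(phantom$density) * phantom$voxel_size^3
}

# Deterministic order-independent checksum used to detect that phase-space
# records and a phantom argument refer to the same geometry.
phantom_checksum <- function(phantom) {
  v <- as.vector(phantom$density)
  s <- sum(v * seq_along(v) %% 97) + sum(as.vector(phantom$material_id)) +
    phantom$voxel_size * 1e4 + sum(phantom$origin * c(3, 5, 7))
  sprintf("%.10e", s)
}

.check_multiple <- function(len, voxel_size, what) {
  n <- len / voxel_size
  if (abs(n - round(n)) > 1e-9)
    stop("grid-mismatch: ", what, " (", len,
         " cm) is not an integer multiple of voxel_size (", voxel_size, " cm)")
  as.integer(round(n))
}

#' Homogeneous water slab phantom
#'
#' A `lateral x lateral x thickness` cm water slab of density 1.0 g/cm^3,
#' centered on the beam axis with its entrance surface at the
#' source-to-surface distance.
#'
#' @param thickness Slab thickness along the beam axis, cm.
#' @param lateral Lateral extent (both x and y), cm.
#' @param voxel_size Isotropic voxel size, cm; must divide both dimensions.
#' @param ssd Source-to-surface distance, cm (default 90).
#' @return A [voxel_phantom()].
#' @export
build_water_slab <- function(thickness, lateral = 40, voxel_size = 1, ssd = 90) {
  stopifnot(thickness > 0, lateral > 0, voxel_size > 0)
  nz <- .check_multiple(thickness, voxel_size, "thickness")
  nl <- .check_multiple(lateral, voxel_size, "lateral extent")
  density <- array(1.0, dim = c(nl, nl, nz))
  voxel_phantom(density, "water", voxel_size,
                origin = c(-lateral / 2, -lateral / 2, ssd))
}

# Shared scaffold for the layered anatomical fixtures: voxel centers are
# classified by deterministic analytic shapes (voxel-center test).  Shape
# centers and semi-axes are deliberately incommensurate with the standard
# voxel sizes so grid-aligned aliasing of the boundaries stays small.
.anatomy_phantom <- function(voxel_size, thickness, lateral, ssd, classify) {
  nz <- .check_multiple(thickness, voxel_size, "thickness")
  nl <- .check_multiple(lateral, voxel_size, "lateral extent")
  origin <- c(-lateral / 2, -lateral / 2, ssd)
  cx <- origin[1] + (seq_len(nl) - 0.5) * voxel_size
  cz <- origin[3] + (seq_len(nz) - 0.5) * voxel_size
  mats <- materials()
  dens_of <- stats::setNames(mats$mass_density_default, mats$name)
  density <- array(0, dim = c(nl, nl, nz))
  material <- array("air", dim = c(nl, nl, nz))
  Y <- outer(rep(1, nl), cx)
  for (k in seq_len(nz)) {
    lab <- classify(outer(cx, rep(1, nl)), Y, cz[k])
    material[, , k] <- lab
    density[, , k] <- dens_of[lab]
  }
  voxel_phantom(density, material, voxel_size, origin)
}

#' Pelvis-like procedural phantom
#'
#' A deterministic 40 x 40 x 20 cm fixture: an elliptical soft-tissue body
#' containing circular cortical-bone inserts (two femoral heads and a
#' sacrum), surrounded by air.  Material inventory: air (0.0012 g/cm^3),
#' soft tissue (1.0), cortical bone (1.85).
#'
#' @inheritParams build_water_slab
#' @return A [voxel_phantom()].
#' @export
build_pelvis_like <- function(voxel_size = 0.5, ssd = 90) {
  zc <- ssd + 10  # body mid-depth
  classify <- function(X, Y, z) {
    u <- z - zc
    lab <- matrix("air", nrow = nrow(X), ncol = ncol(X))
    body <- (X / 17.3)^2 + (u / 9.6)^2 <= 1
    lab[body] <- "soft_tissue"
    bone <- ((X - 8.9)^2 + (u - 1.1)^2 <= 2.3^2) |
      ((X + 8.9)^2 + (u - 1.1)^2 <= 2.3^2) |
      ((X / 3.6)^2 + ((u + 4.1) / 2.6)^2 <= 1)
    lab[body & bone] <- "cortical_bone"
    lab
  }
  .anatomy_phantom(voxel_size, 20, 40, ssd, classify)
}

#' Thorax-like procedural phantom
#'
#' A deterministic 40 x 40 x 20 cm fixture: an elliptical soft-tissue body
#' with two elliptical lung volumes (0.26 g/cm^3), a circular spine and a
#' sternum of cortical bone, surrounded by air.
#'
#' @inheritParams build_water_slab
#' @return A [voxel_phantom()].
#' @export
build_thorax_like <- function(voxel_size = 0.5, ssd = 90) {
  zc <- ssd + 10
  classify <- function(X, Y, z) {
    u <- z - zc
    lab <- matrix("air", nrow = nrow(X), ncol = ncol(X))
    body <- (X / 16.3)^2 + (u / 9.2)^2 <= 1
    lab[body] <- "soft_tissue"
    lungs <- (((X - 6.9) / 5.6)^2 + ((u - 0.3) / 6.15)^2 <= 1) |
      (((X + 6.9) / 5.6)^2 + ((u - 0.3) / 6.15)^2 <= 1)
    lab[body & lungs] <- "lung"
    bone <- (X^2 + (u - 6.1)^2 <= 1.55^2) |
      (abs(X) <= 3.1 & abs(u + 7.9) <= 0.8)
    lab[body & bone] <- "cortical_bone"
    lab
  }
  .anatomy_phantom(voxel_size, 20, 40, ssd, classify)
}

#' Resample a phantom to a commensurate voxel size
#'
#' Coarsening merges blocks of voxels: density is the volume-weighted mean
#' (total mass is preserved); material is the majority label within the
#' block.  Refining replicates voxels.
#'
#' @param phantom A [voxel_phantom()].
#' @param new_voxel_size Target voxel size; must be an integer multiple or
#'   divisor of the current size.
#' @return A [voxel_phantom()].
#' @export
resample_phantom <- function(phantom, new_voxel_size) {
  h <- phantom$voxel_size
  if (abs(new_voxel_size - h) < 1e-12) return(phantom)
  d <- dim(phantom$density)
  mats <- materials()$name
  if (new_voxel_size > h) {
    f <- new_voxel_size / h
    if (abs(f - round(f)) > 1e-9)
      stop("grid-mismatch: sizes are not commensurate")
    f <- as.integer(round(f))
    if (any(d %% f != 0))
      stop("grid-mismatch: grid dims not divisible by coarsening factor")
    nd <- d %/% f
    idx <- function(i) ((i - 1L) %/% f) + 1L
    gx <- idx(seq_len(d[1])); gy <- idx(seq_len(d[2])); gz <- idx(seq_len(d[3]))
    grp <- array(gx + (nd[1]) * ((rep(gy, each = d[1]) - 1L)), dim = d[1:2])
    # accumulate via tapply-free three-level rollup for speed
    dens <- array(0, dim = nd); cnt_mat <- NULL
    newmat <- array("water", dim = nd)
    for (kz in seq_len(nd[3])) {
      sl_d <- phantom$density[, , ((kz - 1L) * f + 1L):(kz * f), drop = FALSE]
      sl_m <- phantom$material_id[, , ((kz - 1L) * f + 1L):(kz * f), drop = FALSE]
      for (ix in seq_len(nd[1])) for (iy in seq_len(nd[2])) {
        xb <- ((ix - 1L) * f + 1L):(ix * f); yb <- ((iy - 1L) * f + 1L):(iy * f)
        dens[ix, iy, kz] <- mean(sl_d[xb, yb, ])
        tb <- tabulate(sl_m[xb, yb, ], nbins = length(mats))
        newmat[ix, iy, kz] <- mats[which.max(tb)]
      }
    }
    voxel_phantom(dens, newmat, new_voxel_size, phantom$origin)
  } else {
    f <- h / new_voxel_size
    if (abs(f - round(f)) > 1e-9)
      stop("grid-mismatch: sizes are not commensurate")
    f <- as.integer(round(f))
    rep_idx <- function(n) rep(seq_len(n), each = f)
    dens <- phantom$density[rep_idx(d[1]), rep_idx(d[2]), rep_idx(d[3]), drop = FALSE]
    matn <- array(mats[phantom$material_id], dim = d)[
      rep_idx(d[1]), rep_idx(d[2]), rep_idx(d[3]), drop = FALSE]
    voxel_phantom(dens, matn, new_voxel_size, phantom$origin)
  }
}

# ---------------------------------------------------------------------------
# Beam and imaging plane

#' Beam geometry
#'
#' Ideal point source at the origin with a divergent rectangular field.
#'
#' @param field_size Field size at the isocenter plane, cm; a single number
#'   (square field) or `c(fx, fy)`.
#' @param spectrum An [energy_spectrum()].
#' @param ssd Source-to-surface distance, cm (default 90).
#' @param sid Source-to-imager distance, cm (default 140).
#' @param iso Source-to-isocenter distance at which `field_size` is defined,
#'   cm (default 100).
#' @return An object of class `beam_geometry`.
#' @export
beam_geometry <- function(field_size, spectrum, ssd = 90, sid = 140, iso = 100) {
  if (length(field_size) == 1L) field_size <- c(field_size, field_size)
  stopifnot(sid > ssd, ssd > 0, all(field_size > 0),
            inherits(spectrum, "energy_spectrum"))
  structure(list(source_position = c(0, 0, 0), ssd = ssd, sid = sid, iso = iso,
                 field_size_at_iso = field_size, spectrum = spectrum),
            class = "beam_geometry")
}

#' Solid angle of the divergent field pyramid
#'
#' Closed form for a rectangle of half-widths `a`, `b` at distance `h`
#' centered on the axis: `4 atan(ab / (h sqrt(a^2 + b^2 + h^2)))`.
#'
#' @param beam A [beam_geometry()].
#' @return Solid angle in steradians.
#' @export
field_solid_angle <- function(beam) {
  a <- beam$field_size_at_iso[1] / 2
  b <- beam$field_size_at_iso[2] / 2
  h <- beam$iso
  4 * atan(a * b / (h * sqrt(a^2 + b^2 + h^2)))
}

#' Point-in-field test
#'
#' TRUE iff the ray from the source through the point lies inside the
#' divergent field pyramid (closed boundary: points exactly on the field
#' edge are inside).
#'
#' @param point A length-3 position (cm) or an `n x 3` matrix of positions.
#' @param beam A [beam_geometry()].
#' @return Logical vector.
#' @export
in_field <- function(point, beam) {
  p <- if (is.matrix(point)) point else matrix(point, ncol = 3)
  fx <- beam$field_size_at_iso[1] / 2
  fy <- beam$field_size_at_iso[2] / 2
  ok <- p[, 3] > 0
  sx <- abs(p[, 1]) * beam$iso / p[, 3]
  sy <- abs(p[, 2]) * beam$iso / p[, 3]
  ok & sx <= fx + 1e-12 & sy <= fy + 1e-12
}

#' Imaging plane
#'
#' A square scoring plane normal to the central axis at the source-to-imager
#' distance, exactly tiled by square pixels.
#'
#' @param extent Plane side length, cm (default 40).
#' @param pixel_size Pixel side length, cm (default 1).
#' @param sid Distance from the source, cm (default 140).
#' @return An object of class `imaging_plane`.
#' @export
imaging_plane <- function(extent = 40, pixel_size = 1, sid = 140) {
  n <- extent / pixel_size
  if (abs(n - round(n)) > 1e-9)
    stop("pixel grid must exactly tile the plane extent")
  n <- as.integer(round(n))
  centers <- -extent / 2 + (seq_len(n) - 0.5) * pixel_size
  structure(list(distance_from_source = sid, extent = extent,
                 pixel_size = pixel_size, n_pixels = n,
                 pixel_centers = centers),
            class = "imaging_plane")
}

#' Pixel center coordinates
#'
#' @param plane An [imaging_plane()].
#' @return An `n^2 x 3` matrix of pixel-center coordinates (cm), x fastest.
#' @export
pixel_coordinates <- function(plane) {
  g <- expand.grid(x = plane$pixel_centers, y = plane$pixel_centers)
  cbind(g$x, g$y, plane$distance_from_source)
}

# ---------------------------------------------------------------------------
# Plain-text phantom container (raw array + sidecar header)

#' Write a phantom as a text array with a JSON sidecar header
#'
#' `path` is created as a directory containing `density.txt` and
#' `material.txt` (one z-slice per block, x fastest within a row) and
#' `header.json` (shape, voxel size, origin, material map; axis order z
#' slowest).
#'
#' @param phantom A [voxel_phantom()].
#' @param path Output directory.
#' @export
write_phantom <- function(phantom, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(phantom$density)
  hdr <- list(shape = d, voxel_size = phantom$voxel_size,
              origin = phantom$origin, axis_order = "z-slowest, x-fastest",
              materials = materials()$name)
  jsonlite::write_json(hdr, file.path(path, "header.json"),
                       auto_unbox = FALSE, digits = NA)
  write(format(as.vector(phantom$density), digits = 15),
        file.path(path, "density.txt"), ncolumns = d[1])
  write(as.vector(phantom$material_id),
        file.path(path, "material.txt"), ncolumns = d[1])
  invisible(path)
}

#' Read a phantom written by [write_phantom()]
#'
#' @param path Directory path.
#' @return A [voxel_phantom()].
#' @export
read_phantom <- function(path) {
  hdr <- jsonlite::read_json(file.path(path, "header.json"), simplifyVector = TRUE)
  d <- as.integer(hdr$shape)
  dens <- array(scan(file.path(path, "density.txt"), quiet = TRUE), dim = d)
  mid <- array(scan(file.path(path, "material.txt"), quiet = TRUE), dim = d)
  voxel_phantom(dens, array(hdr$materials[mid], dim = d), hdr$voxel_size, hdr$origin)
}
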