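# Plain-text container for fluence images: per-image text arrays plus a
# JSON sidecar with the generating metadata.

#' Write an NEF image container
#'
#' Creates a directory with `values.txt` and `number_fluence.txt`
#' (row-per-y-line text arrays, x fastest) and `header.json` (component,
#' plane geometry, sampling metadata).
#'
#' @param nef A [nef_image()].
#' @param path Output directory.
#' @export
write_nef <- function(nef, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  hdr <- list(component = nef$component,
              n_pixels = nef$plane$n_pixels,
              pixel_size = nef$plane$pixel_size,
              extent = nef$plane$extent,
              sid = nef$plane$distance_from_source,
              sampling = nef$sampling)
  jsonlite::write_json(hdr, file.path(path, "header.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  write(format(t(nef$values), digits = 15),
        file.path(path, "values.txt"), ncolumns = ncol(nef$values))
  write(format(t(nef$number_fluence), digits = 15),
        file.path(path, "number_fluence.txt"), ncolumns = ncol(nef$values))
  invisible(path)
}

#' Read an NEF image container written by [write_nef()]
#'
#' @param path Directory path.
#' @return A [nef_image()].
#' @export
read_nef <- function(path) {
  hdr <- jsonlite::read_json(file.path(path, "header.json"),
                             simplifyVector = TRUE)
  pl <- imaging_plane(extent = hdr$extent, pixel_size = hdr$pixel_size,
                      sid = hdr$sid)
  n <- hdr$n_pixels
  v <- t(matrix(scan(file.path(path, "values.txt"), quiet = TRUE), n, n,
                byrow = TRUE))
  nf <- t(matrix(scan(file.path(path, "number_fluence.txt"), quiet = TRUE),
                 n, n, byrow = TRUE))
  nef_image(v, nf, hdr$component, pl,
            sampling = if (is.null(hdr$sampling)) list() else hdr$sampling)
}

#' Cross-plane and in-plane profiles of an image
#'
#' Extracts the central row (cross-plane, along x) and central column
#' (in-plane, along y) through an image, for profile-style comparisons.
#'
#' @param img An [nef_image()] or matrix.
#' @param plane The [imaging_plane()] (needed when `img` is a matrix).
#' @return A data.frame with columns `position_cm`, `cross_plane`,
#'   `in_plane`.
#' @export
nef_profiles <- function(img, plane = NULL) {
  if (inherits(img, "nef_image")) { plane <- img$plane; img <- img$values }
  if (is.null(plane)) stop("plane is required for matrix input")
  mid <- ceiling(plane$n_pixels / 2)
  data.frame(position_cm = plane$pixel_centers,
             cross_plane = img[, mid],
             in_plane = img[mid, ])
}
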