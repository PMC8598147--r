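# Validation metrics (percent-difference images, relative RMSE, efficiency,
# error budgets, mean-energy overlap), tri-hybrid assembly with recommended
# settings, and the sampling-sweep driver.

.image_of <- function(x) {
  if (inherits(x, "nef_image")) x$values
  else if (is.matrix(x)) x
  else stop("expected an nef_image or a matrix")
}

#' Percent-difference image summary
#'
#' Per-pixel percent difference `100 (th - mc) / reference`; its mean over
#' included pixels is the accuracy and its standard deviation the
#' precision.  The default reference is the comparison image itself; for
#' component comparisons pass the oracle total-scatter image so component
#' errors are expressed as percent of total patient scatter.  Pixels whose
#' oracle relative statistical sigma exceeds `max_rel_sigma` are excluded
#' and counted, so oracle noise is not mistaken for estimator error.
#'
#' @param th Predicted image ([nef_image()] or matrix).
#' @param mc Gold-standard image (matrix or [nef_image()]).
#' @param reference Denominator image (default `mc`).
#' @param rel_sigma Optional per-pixel relative sigma of `mc` (matrix).
#' @param max_rel_sigma Exclusion threshold on `rel_sigma` (default `Inf`).
#' @return An object of class `pdi_summary`: `pdi` (matrix, `NA` where
#'   excluded), `accuracy` (%), `precision` (%), `n_included`, `n_excluded`.
#' @export
percent_difference_summary <- function(th, mc, reference = NULL,
                                       rel_sigma = NULL,
                                       max_rel_sigma = Inf) {
  th <- .image_of(th); mc <- .image_of(mc)
  reference <- if (is.null(reference)) mc else .image_of(reference)
  stopifnot(all(dim(th) == dim(mc)), all(dim(reference) == dim(mc)))
  include <- reference > 0
  if (!is.null(rel_sigma))
    include <- include & !is.na(rel_sigma) & rel_sigma < max_rel_sigma
  if (!any(include)) stop("empty-comparison: all pixels masked")
  pdi <- matrix(NA_real_, nrow(th), ncol(th))
  pdi[include] <- 100 * (th[include] - mc[include]) / reference[include]
  structure(list(pdi = pdi,
                 accuracy = mean(pdi[include]),
                 precision = stats::sd(pdi[include]),
                 n_included = sum(include),
                 n_excluded = sum(!include)),
            class = "pdi_summary")
}

#' @export
print.pdi_summary <- function(x, ...) {
  cat(sprintf("<pdi_summary> accuracy %.3f%%, precision %.3f%% (%d pixels, %d excluded)\n",
              x$accuracy, x$precision, x$n_included, x$n_excluded))
  invisible(x)
}

#' Relative root mean square error
#'
#' `sqrt( (1/N) sum_i ((x_i^TH - x_i^MC) / x_i^MC)^2 )` over included
#' pixels.
#'
#' @param th,mc Congruent images ([nef_image()] or matrices).
#' @param include Optional logical matrix of pixels to include (default:
#'   all).
#' @return Dimensionless rRMSE (multiply by 100 for %).
#' @export
rrmse <- function(th, mc, include = NULL) {
  th <- .image_of(th); mc <- .image_of(mc)
  stopifnot(all(dim(th) == dim(mc)))
  if (is.null(include)) include <- matrix(TRUE, nrow(mc), ncol(mc))
  if (any(mc[include] == 0)) stop("zero gold-standard pixel in included set")
  sqrt(mean(((th[include] - mc[include]) / mc[include])^2))
}

#' Computational efficiency figure of merit
#'
#' `epsilon = 1 / (t_cpu * rRMSE^2)`.
#'
#' @param t_cpu CPU time in seconds (> 0).
#' @param rrmse Relative RMSE, dimensionless (> 0).
#' @return A list of class `efficiency_result` with `rrmse`, `t_cpu`,
#'   `epsilon`.
#' @export
efficiency <- function(t_cpu, rrmse) {
  if (t_cpu <= 0 || rrmse <= 0) stop("t_cpu and rrmse must be > 0")
  structure(list(rrmse = rrmse, t_cpu = t_cpu,
                 epsilon = 1 / (t_cpu * rrmse^2)),
            class = "efficiency_result")
}

#' Scatter-component error budget
#'
#' Given the fluence fraction carried by each scatter component and a
#' per-component share of the total-scatter error, the allowed percentage
#' error on a component is `share / fraction`, and the corresponding total
#' error is the quadrature sum of the shares.  With fractions
#' (0.70, 0.20, 0.10) and a 1% share this yields 1.4%, 5%, 10% and a total
#' of about 1.7%.
#'
#' @param fractions Named or ordered fractions for (single, multiple, eig);
#'   positive, summing to 1.
#' @param per_component_target Per-component share of total-scatter error
#'   in %, scalar or one per component (default 1).
#' @return A list of class `error_budget`: `component_fractions`,
#'   `tolerances` (%; named single/multiple/eig), `sigma_total` (%).
#' @export
error_budget <- function(fractions = c(single = 0.70, multiple = 0.20, eig = 0.10),
                         per_component_target = 1) {
  if (any(fractions <= 0)) stop("fractions must be > 0")
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  target <- rep_len(per_component_target, length(fractions))
  tol <- target / fractions
  names(tol) <- names(fractions)
  structure(list(component_fractions = fractions,
                 tolerances = tol,
                 sigma_total = sqrt(sum(target^2))),
            class = "error_budget")
}

#' Overlap of two pixel-wise mean-energy histograms
#'
#' Histograms both images' per-pixel mean energies on a shared grid of
#' `bin_width` MeV bins anchored at 0, unit-normalizes the histograms, and
#' returns `sum_bins min(hA, hB)`, a number in [0, 1].  Symmetric in its
#' arguments.
#'
#' @param a,b Congruent matrices of per-pixel mean energy (MeV); `NA`
#'   pixels are dropped pairwise.
#' @param bin_width Histogram bin width in MeV (default 0.05).
#' @return Overlap fraction in [0, 1].
#' @export
mean_energy_overlap <- function(a, b, bin_width = 0.05) {
  keep <- !is.na(a) & !is.na(b)
  va <- a[keep]; vb <- b[keep]
  if (length(va) == 0) return(NA_real_)
  lo <- floor(min(va, vb) / bin_width)
  hi <- ceiling(max(va, vb) / bin_width + 1e-9)
  breaks <- (lo:hi) * bin_width
  ha <- hist(va, breaks = breaks, plot = FALSE)$counts
  hb <- hist(vb, breaks = breaks, plot = FALSE)$counts
  sum(pmin(ha / sum(ha), hb / sum(hb)))
}

#' Recommended sampling settings
#'
#' The recommended operating point: 0.5 cm integration voxels below a
#' 10 x 10 cm^2 field and 1 cm at or above it, 1 MeV energy bins, 20 K
#' phase-space histories, no scatter-order truncation, and 0.5 cm pencil
#' sampling for the kernel superposition.
#'
#' @param field_size Field size at isocenter, cm (scalar or length 2).
#' @return A named list of settings.
#' @export
recommended_settings <- function(field_size) {
  fs <- max(field_size)
  list(voxel_size = if (fs < 10) 0.5 else 1,
       energy_bin_size = 1,
       mchhb = 20000,
       order_range = order_range(2, Inf),
       pbsk_resolution = 0.5)
}

#' Tri-hybrid total scatter NEF
#'
#' Runs the three component estimators (analytic single scatter, hybrid
#' multiple scatter, kernel-superposition EIG) and sums them pixel-wise.
#' Settings not supplied fall back to [recommended_settings()] for the
#' beam's field size.
#'
#' @param phantom A [voxel_phantom()].
#' @param beam A [beam_geometry()].
#' @param plane An [imaging_plane()].
#' @param settings Named list; recognized keys `voxel_size`,
#'   `energy_bin_size`, `mchhb`, `order_range`, `pbsk_resolution`, `seed`
#'   (required), `kernel_library` (a [build_kernel_library()]; omit to skip
#'   the EIG component), `coverage` (passed to [compute_eig_nef()]).
#' @return A list of class `th_result`: `total`, `single`, `multiple`,
#'   `eig` ([nef_image()]s), `timings` (seconds per stage), `settings`.
#' @export
compute_total_th <- function(phantom, beam, plane, settings = list()) {
  def <- recommended_settings(beam$field_size_at_iso)
  s <- utils::modifyList(def, settings)
  seed <- .check_seed(s$seed)
  timings <- c(single = NA_real_, multiple = NA_real_, eig = NA_real_)
  t0 <- proc.time()[["elapsed"]]
  single <- compute_single_scatter_nef(phantom, beam, plane,
                                       voxel_size = s$voxel_size,
                                       energy_bin_size = s$energy_bin_size)
  timings["single"] <- proc.time()[["elapsed"]] - t0
  t0 <- proc.time()[["elapsed"]]
  records <- run_phase_space_extraction(beam, phantom, s$mchhb, seed)
  multiple <- compute_multiple_scatter_nef(records, phantom, plane,
                                           range = s$order_range)
  timings["multiple"] <- proc.time()[["elapsed"]] - t0
  t0 <- proc.time()[["elapsed"]]
  if (!is.null(s$kernel_library)) {
    eig <- compute_eig_nef(phantom, beam, plane, s$kernel_library,
                           sampling_resolution = s$pbsk_resolution,
                           coverage = if (is.null(s$coverage)) "error" else s$coverage)
  } else {
    z <- matrix(0, plane$n_pixels, plane$n_pixels)
    eig <- nef_image(z, z, "eig", plane)
  }
  timings["eig"] <- proc.time()[["elapsed"]] - t0
  tot <- nef_image(single$values + multiple$values + eig$values,
                   single$number_fluence + multiple$number_fluence + eig$number_fluence,
                   "total", plane,
                   sampling = list(voxel_size = s$voxel_size,
                                   energy_bin_size = s$energy_bin_size,
                                   mchhb = s$mchhb,
                                   order_range = s$order_range,
                                   pbsk_resolution = s$pbsk_resolution,
                                   seed = seed))
  structure(list(total = tot, single = single, multiple = multiple, eig = eig,
                 timings = timings, settings = s),
            class = "th_result")
}

#' @export
print.th_result <- function(x, ...) {
  cat(sprintf(paste0("<th_result> mean NEF: total %.4g (single %.4g, ",
                     "multiple %.4g, eig %.4g); t = %.1f s\n"),
              mean(x$total$values), mean(x$single$values),
              mean(x$multiple$values), mean(x$eig$values),
              sum(x$timings, na.rm = TRUE)))
  invisible(x)
}

#' Sampling sweep driver
#'
#' Runs the tri-hybrid method over a grid of sampling settings and compares
#' each run against a fixed gold standard, producing one row per cell with
#' accuracy, precision, rRMSE, CPU time and efficiency.
#'
#' @param config A list with elements:
#'   `phantom`, `beam`, `plane` (the fixed geometry);
#'   `cells` (data.frame with any of the columns `voxel_size`,
#'   `energy_bin_size`, `mchhb`, `seed`);
#'   `oracle` (a [run_full_mc_oracle()] result) or `reference` (an
#'   [nef_image()] or matrix, e.g. a fine-sampling internal reference);
#'   optional `reference_denominator` (matrix), `max_rel_sigma`,
#'   `components` (`"total"` default, or `"single"` to sweep the analytic
#'   stage alone), `kernel_library`, `coverage`.
#' @param csv Optional path; when given the results table is also written
#'   as CSV.
#' @return A data.frame with one row per cell: the cell's settings plus
#'   `accuracy`, `precision`, `rrmse`, `t_cpu`, `epsilon`, `n_excluded`.
#' @export
run_sampling_sweep <- function(config, csv = NULL) {
  required <- c("phantom", "beam", "plane", "cells")
  missing_keys <- setdiff(required, names(config))
  if (length(missing_keys) > 0)
    stop("invalid config: missing keys ", paste(missing_keys, collapse = ", "))
  known <- c(required, "oracle", "reference", "reference_denominator",
             "max_rel_sigma", "components", "kernel_library", "coverage")
  bad <- setdiff(names(config), known)
  if (length(bad) > 0)
    stop("invalid config keys: ", paste(bad, collapse = ", "))
  components <- if (is.null(config$components)) "total" else config$components
  if (!is.null(config$oracle)) {
    mc_img <- config$oracle$nef$scatter
    rel_sigma <- config$oracle$rel_sigma$scatter
  } else {
    mc_img <- .image_of(config$reference)
    rel_sigma <- NULL
  }
  denom <- if (is.null(config$reference_denominator)) mc_img
           else .image_of(config$reference_denominator)
  mrs <- if (is.null(config$max_rel_sigma)) Inf else config$max_rel_sigma
  cells <- config$cells
  rows <- lapply(seq_len(nrow(cells)), function(r) {
    cell <- as.list(cells[r, , drop = FALSE])
    t0 <- proc.time()[["elapsed"]]
    if (components == "single") {
      img <- compute_single_scatter_nef(config$phantom, config$beam,
                                        config$plane,
                                        voxel_size = cell$voxel_size,
                                        energy_bin_size = cell$energy_bin_size)
    } else {
      st <- cell
      st$kernel_library <- config$kernel_library
      st$coverage <- config$coverage
      img <- compute_total_th(config$phantom, config$beam, config$plane,
                              settings = st)$total
    }
    t_cpu <- proc.time()[["elapsed"]] - t0
    pdi <- percent_difference_summary(img, mc_img, reference = denom,
                                      rel_sigma = rel_sigma,
                                      max_rel_sigma = mrs)
    inc <- denom > 0 & mc_img > 0
    if (!is.null(rel_sigma)) inc <- inc & !is.na(rel_sigma) & rel_sigma < mrs
    rr <- rrmse(img, mc_img, include = inc)
    cbind(as.data.frame(cell),
          data.frame(accuracy = pdi$accuracy, precision = pdi$precision,
                     rrmse = rr, t_cpu = t_cpu,
                     epsilon = 1 / (max(t_cpu, 1e-6) * rr^2),
                     n_excluded = pdi$n_excluded))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(csv)) utils::write.csv(out, csv, row.names = FALSE)
  out
}
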