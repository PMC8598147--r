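# The desk-scale photon Monte Carlo engine: full-transport oracle with
# scatter-category tagging, phase-space extraction for the hybrid method,
# and detailed single-history transport for diagnostics.
#
# Source model: one photon per history emitted from the point source,
# uniformly per solid angle within the divergent field pyramid.  Tallies are
# converted to the per-isotropic-source-photon convention by the factor
# Omega/4pi, so they share the normalization of the analytic estimators.

.mc_opts <- function(tally = FALSE, record = FALSE, pencil = FALSE,
                     per_history = FALSE, cutoff = 0.05, n_batches = 25L,
                     pencil_origin = c(0, 0, 0)) {
  list(tally = tally, record = record, pencil = pencil,
       per_history = per_history, cutoff = cutoff,
       n_batches = as.integer(n_batches),
       pencil_origin = as.numeric(pencil_origin))
}

#' Transport photon histories with full bookkeeping
#'
#' Runs a small number of analog histories and returns the per-history
#' energy ledger (energy reaching the plane, absorbed, escaped), the number
#' of Compton interactions, the exit scatter order, and the multiple-scatter
#' interaction records.  Intended for inspection and testing; use
#' [run_full_mc_oracle()] for production tallies.
#'
#' @param beam A [beam_geometry()].
#' @param phantom A [voxel_phantom()].
#' @param seed Explicit RNG seed (required).
#' @param n_histories Number of histories (default 1).
#' @param plane An [imaging_plane()] used for crossing classification.
#' @param cutoff Photon energy cutoff in MeV (default 0.05); photons below
#'   it are terminated with their energy booked as local absorption.
#' @return A list: `history` (matrix, one row per history with columns
#'   `E0`, `plane`, `absorbed`, `escaped`, `n_compton`, `exit_order`),
#'   `records` (phase-space matrix as in [run_phase_space_extraction()]),
#'   and `max_history_relerr` (worst per-history energy-conservation error).
#' @export
transport_history <- function(beam, phantom, seed, n_histories = 1,
                              plane = imaging_plane(sid = beam$sid),
                              cutoff = 0.05) {
  seed <- .check_seed(seed)
  res <- cpp_mc_run(.grid_list(phantom), .xs_list(), .beam_list(beam),
                    .plane_list(plane), n_histories, seed,
                    .mc_opts(record = TRUE, per_history = TRUE, cutoff = cutoff))
  list(history = res$history, records = res$records,
       max_history_relerr = res$max_history_relerr,
       energy_ledger = res$energy_ledger)
}

#' Extract multiple-scatter phase space
#'
#' Runs `n_histories` analog histories and records, at every Compton vertex
#' whose outgoing photon has scatter order >= 2 (and which is not an
#' electron-interaction-generated photon), the pre-collision phase space:
#' site, incoming direction, incoming energy, statistical weight and the
#' outgoing scatter order.  Records are bit-exact reproducible for a given
#' seed.
#'
#' @inheritParams transport_history
#' @param n_histories Number of MC histories (MCHHB).
#' @return A numeric matrix with columns `x, y, z, ux, uy, uz, E, w, order`
#'   and attributes `n_histories`, `solid_angle`, `phantom_checksum`,
#'   `order_histogram` and `seed`.
#' @export
run_phase_space_extraction <- function(beam, phantom, n_histories, seed,
                                       cutoff = 0.05) {
  seed <- .check_seed(seed)
  stopifnot(n_histories >= 0)
  plane <- imaging_plane(sid = beam$sid)
  if (n_histories == 0) {
    rec <- matrix(numeric(0), ncol = 9)
  } else {
    res <- cpp_mc_run(.grid_list(phantom), .xs_list(), .beam_list(beam),
                      .plane_list(plane), n_histories, seed,
                      .mc_opts(record = TRUE, cutoff = cutoff))
    rec <- res$records
    attr(rec, "order_histogram") <- res$order_histogram
  }
  colnames(rec) <- c("x", "y", "z", "ux", "uy", "uz", "E", "w", "order")
  attr(rec, "n_histories") <- n_histories
  attr(rec, "solid_angle") <- field_solid_angle(beam)
  attr(rec, "phantom_checksum") <- phantom_checksum(phantom)
  attr(rec, "incident_energy_fluence") <- incident_energy_fluence(beam)
  attr(rec, "seed") <- seed
  rec
}

#' Full Monte Carlo oracle with scatter-category tagging
#'
#' Analog photon transport scoring the energy fluence crossing the imaging
#' plane, partitioned into primary (order 0), single (order 1), multiple
#' (order >= 2) and EIG (positron-annihilation-originated) categories, with
#' per-pixel fluence-weighted mean energy and a batch-based statistical
#' uncertainty estimate.  This plays the role of the gold standard against
#' which the tri-hybrid prediction is validated.
#'
#' @inheritParams transport_history
#' @param plane The scoring [imaging_plane()].
#' @param n_histories Number of histories (rounded up to a multiple of
#'   `n_batches`).
#' @param n_batches Number of batches for the variance estimate (default 25).
#' @return An object of class `scored_fluence`: a list with `nef` (named
#'   list of pixel matrices of normalized energy fluence for `primary`,
#'   `single`, `multiple`, `eig`, `scatter` = single+multiple+eig, and
#'   `total`), `number_fluence` (same normalization), `mean_energy`
#'   (per-pixel, MeV, for each category and for total scatter), `rel_sigma`
#'   (per-pixel relative statistical sigma per category and for scatter),
#'   `n_histories`, `energy_ledger`, `max_history_relerr`, exit-order
#'   statistics, and the generating seed.
#' @export
run_full_mc_oracle <- function(beam, phantom, plane, n_histories, seed,
                               n_batches = 25, cutoff = 0.05) {
  seed <- .check_seed(seed)
  n_batches <- as.integer(n_batches)
  n <- as.numeric(ceiling(n_histories / n_batches) * n_batches)
  res <- cpp_mc_run(.grid_list(phantom), .xs_list(), .beam_list(beam),
                    .plane_list(plane), n, seed,
                    .mc_opts(tally = TRUE, cutoff = cutoff,
                             n_batches = n_batches))
  omega <- field_solid_angle(beam)
  inc <- incident_energy_fluence(beam)
  scale <- (omega / (4 * pi)) / (n * plane$pixel_size^2) / inc
  cats <- c("primary", "single", "multiple", "eig")
  nef <- nf <- rs <- stats::setNames(vector("list", 4), cats)
  for (i in 1:4) {
    nef[[i]] <- .as_plane_matrix(res$EF[, i] * scale, plane)
    nf[[i]] <- .as_plane_matrix(res$NF[, i] * scale, plane)
    rs[[i]] <- .as_plane_matrix(res$rel_sigma[, i], plane)
  }
  nef$scatter <- nef$single + nef$multiple + nef$eig
  nef$total <- nef$scatter + nef$primary
  nf$scatter <- nf$single + nf$multiple + nf$eig
  nf$total <- nf$scatter + nf$primary
  # scatter-category statistical sigma: combine per-category batch sigmas in
  # quadrature on the absolute scale
  abs_sig <- function(cat) ifelse(is.na(rs[[cat]]), 0, rs[[cat]] * nef[[cat]])
  sc_sig <- sqrt(abs_sig("single")^2 + abs_sig("multiple")^2 + abs_sig("eig")^2)
  rs$scatter <- ifelse(nef$scatter > 0, sc_sig / nef$scatter, NA_real_)
  mean_energy <- lapply(c(cats, "scatter", "total"), function(cn)
    ifelse(nf[[cn]] > 0, nef[[cn]] / nf[[cn]], NA_real_))
  names(mean_energy) <- c(cats, "scatter", "total")
  structure(list(nef = nef, number_fluence = nf, mean_energy = mean_energy,
                 rel_sigma = rs, n_histories = n,
                 energy_ledger = res$energy_ledger,
                 max_history_relerr = res$max_history_relerr,
                 exit_order_mean = if (res$exit_order_n > 0)
                   res$exit_order_sum / res$exit_order_n else NA_real_,
                 compton_per_interacting_history =
                   res$compton_events / max(res$histories_with_compton, 1),
                 compton_per_history = res$compton_events / n,
                 order_histogram = res$order_histogram,
                 incident_energy_fluence = inc, solid_angle = omega,
                 phantom_checksum = phantom_checksum(phantom),
                 seed = seed),
            class = "scored_fluence")
}

#' @export
print.scored_fluence <- function(x, ...) {
  cat(sprintf(paste0("<scored_fluence> %g histories; mean scatter NEF %.4g; ",
                     "max per-pixel rel sigma (scatter) %.3g\n"),
              x$n_histories, mean(x$nef$scatter),
              max(x$rel_sigma$scatter, na.rm = TRUE)))
  invisible(x)
}
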