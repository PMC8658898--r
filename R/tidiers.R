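# broom-style tidiers and re-exports.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an ensemble into per-sample centroid coordinates
#'
#' @param x An `rp_ensemble`.
#' @param ... Unused.
#' @return A tibble with columns `sample`, `atom`, `label`, `x`, `y`, `z`
#'   (angstrom).
#' @export
tidy.rp_ensemble <- function(x, ...) {
  ctr <- .ensemble_centroid_matrix(x) # ndof x n_samples (bohr)
  purrr::map_dfr(seq_len(ncol(ctr)), function(s) {
    g <- from_au(.unflatten_geometry(ctr[, s]), "length")
    tibble::tibble(sample = s, atom = seq_len(x$n_atoms), label = x$labels,
                   x = g[, 1], y = g[, 2], z = g[, 3])
  })
}

#' @rdname tidy.rp_ensemble
#' @return For `glance`: a one-row tibble with sample counts, bead count,
#'   temperature and the mean diagnostic temperature estimate.
#' @export
glance.rp_ensemble <- function(x, ...) {
  tibble::tibble(
    n_samples = length(x$samples), n_atoms = x$n_atoms, n_beads = x$n_beads,
    temperature_k = x$thermo$temperature,
    mean_temperature_estimate_k = if (nrow(x$diagnostics) > 0) {
      mean(x$diagnostics$temperature)
    } else NA_real_,
    seed = x$provenance$seed
  )
}

#' Tidy a trajectory into long per-frame, per-atom records
#'
#' @param x An `rp_trajectory`.
#' @param ... Unused.
#' @return A tibble with `frame`, `time_fs`, `atom`, `label`, `x`, `y`,
#'   `z` (angstrom), `vx`, `vy`, `vz` (angstrom/fs) and `hamiltonian_ev`.
#' @export
tidy.rp_trajectory <- function(x, ...) {
  n_frames <- length(x$time_fs)
  n_atoms <- length(x$labels)
  purrr::map_dfr(seq_len(n_frames), function(f) {
    g <- .unflatten_geometry(x$centroid_positions[f, ])
    v <- .unflatten_geometry(x$centroid_velocities[f, ])
    tibble::tibble(frame = f, time_fs = x$time_fs[f],
                   atom = seq_len(n_atoms), label = x$labels,
                   x = g[, 1], y = g[, 2], z = g[, 3],
                   vx = v[, 1], vy = v[, 2], vz = v[, 3],
                   hamiltonian_ev = x$hamiltonian_ev[f])
  })
}

#' @rdname tidy.rp_trajectory
#' @export
glance.rp_trajectory <- function(x, ...) {
  drift <- if (abs(x$hamiltonian_ev[1]) > 0) {
    max(abs(x$hamiltonian_ev - x$hamiltonian_ev[1])) /
      abs(x$hamiltonian_ev[1])
  } else max(abs(x$hamiltonian_ev - x$hamiltonian_ev[1]))
  tibble::tibble(n_frames = length(x$time_fs), t_max_fs = max(x$time_fs),
                 status = x$status, e_b = x$e_b,
                 relative_hamiltonian_drift = drift)
}

#' @rdname tidy.rp_trajectory
#' @export
glance.rp_trajectory_set <- function(x, ...) {
  purrr::imap_dfr(x$trajectories, function(tr, i) {
    dplyr::mutate(glance(tr), trajectory = i, .before = 1)
  })
}

#' Tidy a spectrum histogram
#'
#' @param x An `rp_spectrum`.
#' @param ... Unused.
#' @return The histogram tibble (`e_b` bin mids in eV, normalized
#'   `density`).
#' @export
tidy.rp_spectrum <- function(x, ...) x$table

#' @rdname tidy.rp_spectrum
#' @export
glance.rp_spectrum <- function(x, ...) {
  tibble::tibble(sample_count = x$sample_count, convention = x$convention,
                 mean_ev = x$mean_ev, sd_ev = x$sd_ev)
}

#' Tidy a coincidence histogram
#'
#' @param x An `rp_coincidence`.
#' @param ... Unused.
#' @return Long tibble with `e_k`, `e_b` bin mids (eV) and `count`.
#' @export
tidy.rp_coincidence <- function(x, ...) x$table
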