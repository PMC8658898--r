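# Programmatic fixture generators: synthetic ensembles and constructed
# trajectories with exactly known properties, used by tests and examples.
# All are ordinary package functionality (e.g. a Gaussian ensemble is the
# analytic reference density for the reflection principle).

#' Synthetic Gaussian ensemble
#'
#' An `rp_ensemble` whose bead positions are drawn i.i.d. from an isotropic
#' Gaussian around a center — the exactly solvable reference density for
#' spectral mapping (a linear gap over a Gaussian density gives a Gaussian
#' spectrum of width `|slope| * sigma`).
#'
#' @param n_samples Number of ensemble members.
#' @param sigma Position standard deviation, angstrom.
#' @param center `n_atoms x 3` matrix of means, angstrom.
#' @param masses Atomic masses, amu.
#' @param n_beads Beads per member.
#' @param temperature Nominal temperature tag, K.
#' @param seed Integer seed.
#' @return An `rp_ensemble`.
#' @export
gaussian_ensemble <- function(n_samples, sigma, center = matrix(0, 1, 3),
                              masses = rep(1, nrow(center)), n_beads = 1L,
                              temperature = 300, seed = 1L) {
  stopifnot(n_samples >= 1, sigma > 0, is.matrix(center), ncol(center) == 3L)
  set.seed(seed)
  ndof <- 3L * nrow(center)
  mu <- to_au(.flatten_geometry(center), "length")
  sd_au <- to_au(sigma, "length")
  samples <- lapply(seq_len(n_samples), function(i) {
    list(positions = mu + matrix(stats::rnorm(ndof * n_beads, sd = sd_au),
                                 ndof, n_beads),
         momenta = matrix(0, ndof, n_beads))
  })
  structure(
    list(samples = samples, n_atoms = nrow(center), n_beads = as.integer(n_beads),
         masses = to_au(masses, "mass"),
         labels = paste0("X", seq_len(nrow(center))),
         thermo = thermo_context(temperature = temperature),
         diagnostics = tibble::tibble(),
         provenance = list(seed = seed, config_hash = "synthetic-gaussian")),
    class = "rp_ensemble"
  )
}

#' Constructed two-fragment trajectory
#'
#' Builds an `rp_trajectory` of two point fragments with a prescribed
#' relative-speed time series, for exercising plateau detection and timing
#' analysis against exactly known answers. Fragment A stays at the origin;
#' fragment B moves along +x with the given speed profile.
#'
#' @param speeds Relative speed at each frame, angstrom/fs.
#' @param dt Frame spacing, fs.
#' @param masses Two masses, amu.
#' @param d0 Initial separation, angstrom.
#' @return An `rp_trajectory` with `status = "max_time"`.
#' @export
synthetic_two_body_trajectory <- function(speeds, dt = 0.3,
                                          masses = c(1, 1), d0 = 1.5) {
  n <- length(speeds)
  stopifnot(n >= 2, dt > 0, all(speeds >= 0))
  x_b <- d0 + cumsum(c(0, speeds[-n])) * dt
  pos <- cbind(0, 0, 0, x_b, 0, 0)
  vel <- cbind(0, 0, 0, speeds, 0, 0)
  final_pos <- matrix(c(0, 0, 0, x_b[n], 0, 0), 6L, 1L)
  m_au <- to_au(masses, "mass")
  final_mom <- matrix(c(0, 0, 0, to_au(speeds[n], "velocity") * m_au[2], 0, 0),
                      6L, 1L)
  final <- structure(
    list(n_atoms = 2L, n_beads = 1L, masses = m_au, labels = c("A", "B"),
         positions = to_au(final_pos, "length"), momenta = final_mom),
    class = "bead_configuration")
  structure(
    list(id = 1L, e_b = NA_real_, time_fs = (seq_len(n) - 1L) * dt,
         centroid_positions = pos, centroid_velocities = vel,
         hamiltonian_ev = rep(0, n), status = "max_time", n_steps = n - 1L,
         dt_fs = dt, final = final, masses_amu = masses,
         labels = c("A", "B"), bead_frames = NULL),
    class = "rp_trajectory"
  )
}
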