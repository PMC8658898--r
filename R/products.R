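# Per-trajectory product observables: fragment kinetic-energy release from
# centroid velocities, the signed H-O-C-O-style dihedral for cis/trans
# channel assignment, dissociation timing from the relative-velocity
# plateau, and the Boltzmann isomer-ratio helper.

#' Fragment definition
#'
#' Two disjoint, nonempty atom-index sets naming the product fragments.
#'
#' @param a,b Integer atom indices.
#' @return A list of class `fragment_definition`.
#' @export
fragment_definition <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  if (length(a) == 0L || length(b) == 0L) {
    rlang::abort("both fragments must be nonempty", class = "rpdyn_state_error")
  }
  if (length(intersect(a, b)) > 0L) {
    rlang::abort("fragments must be disjoint", class = "rpdyn_state_error")
  }
  structure(list(a = a, b = b), class = "fragment_definition")
}

.as_fragments <- function(fragments) {
  if (inherits(fragments, "fragment_definition")) return(fragments)
  fragment_definition(fragments$a, fragments$b)
}

#' Relative (fragment) kinetic-energy release
#'
#' \eqn{E_k = \tfrac12 \mu |v_A - v_B|^2} with \eqn{v_A, v_B} the
#' mass-weighted center-of-mass velocities of the two fragments (computed
#' from atomic centroid velocities) and \eqn{\mu = M_A M_B / (M_A + M_B)}
#' the reduced mass. Invariant under a uniform boost of all velocities.
#'
#' @param velocities `n_atoms x 3` centroid velocities, angstrom/fs
#'   (see [centroid_velocities()]).
#' @param masses Atomic masses, amu.
#' @param fragments A [fragment_definition()] or list with `a`, `b`.
#' @return Kinetic-energy release in eV.
#' @export
relative_kinetic_energy <- function(velocities, masses, fragments) {
  fragments <- .as_fragments(fragments)
  stopifnot(is.matrix(velocities), ncol(velocities) == 3L,
            length(masses) == nrow(velocities))
  com_v <- function(idx) {
    colSums(velocities[idx, , drop = FALSE] * masses[idx]) / sum(masses[idx])
  }
  ma <- sum(masses[fragments$a])
  mb <- sum(masses[fragments$b])
  mu <- ma * mb / (ma + mb)
  v_rel2 <- sum((com_v(fragments$a) - com_v(fragments$b))^2)
  # mu [amu] * v^2 [(angstrom/fs)^2] -> atomic units -> eV
  ek_au <- to_au(mu, "mass") * to_au(1, "velocity")^2 * v_rel2 / 2
  from_au(ek_au, "energy")
}

#' Signed dihedral (torsion) angle
#'
#' The torsion about the j-k axis, with the sign fixed by the right-hand
#' rule: positive when the l atom is rotated counterclockwise from the
#' i atom looking down j to k. Returned in degrees in \eqn{(-180, 180]}.
#'
#' @param geometry `n_atoms x 3` coordinate matrix (any length unit).
#' @param i,j,k,l Distinct atom indices.
#' @return Angle in degrees.
#' @export
dihedral_angle <- function(geometry, i, j, k, l) {
  idx <- c(i, j, k, l)
  stopifnot(is.matrix(geometry), ncol(geometry) == 3L,
            length(unique(idx)) == 4L, all(idx >= 1),
            all(idx <= nrow(geometry)))
  b1 <- geometry[j, ] - geometry[i, ]
  b2 <- geometry[k, ] - geometry[j, ]
  b3 <- geometry[l, ] - geometry[k, ]
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  m <- cr(b1, b2)
  n <- cr(b2, b3)
  if (sqrt(sum(m^2)) < 1e-10 * sqrt(sum(b1^2) * sum(b2^2)) ||
      sqrt(sum(n^2)) < 1e-10 * sqrt(sum(b2^2) * sum(b3^2))) {
    rlang::abort("undefined torsion: three consecutive atoms are collinear",
                 class = "rpdyn_geometry_error")
  }
  phi <- atan2(sum(cr(m, n) * b2) / sqrt(sum(b2^2)), sum(m * n))
  deg <- phi * 180 / pi
  if (deg <= -180) deg <- deg + 360
  deg
}

#' Map a dihedral to the reporting range (-90, 270]
#'
#' Shifting the branch cut to -90 degrees keeps the trans band
#' (around 180 degrees) contiguous in histograms and tables.
#'
#' @param phi Angle(s) in degrees (any branch).
#' @return Angle(s) in (-90, 270].
#' @export
report_dihedral <- function(phi) {
  out <- phi %% 360
  ifelse(out > 270, out - 360, out)
}

#' Classify the torsional product channel
#'
#' `cis` if the reported dihedral lies in \eqn{(-90, 90]}, `trans` if in
#' \eqn{(90, 270]}: a symmetric decision boundary between the two bands
#' observed in dissociative photodetachment (trans products near 150-210
#' degrees, cis products near -45 to 45 degrees).
#'
#' @param phi Dihedral angle(s) in degrees, any branch.
#' @return Character vector, `"cis"` or `"trans"`.
#' @export
classify_channel <- function(phi) {
  stopifnot(all(is.finite(phi)))
  ifelse(report_dihedral(phi) <= 90, "cis", "trans")
}

# fragment COM separation / relative speed series from a trajectory
.trajectory_fragment_series <- function(traj, fragments) {
  fragments <- .as_fragments(fragments)
  m <- traj$masses_amu
  n_frames <- length(traj$time_fs)
  com_series <- function(x, idx) {
    w <- m[idx] / sum(m[idx])
    out <- matrix(0, n_frames, 3L)
    for (t in seq_along(idx)) {
      out <- out + w[t] * x[, .rows3(idx[t]), drop = FALSE]
    }
    out
  }
  dpos <- com_series(traj$centroid_positions, fragments$a) -
    com_series(traj$centroid_positions, fragments$b)
  dvel <- com_series(traj$centroid_velocities, fragments$a) -
    com_series(traj$centroid_velocities, fragments$b)
  list(separation = sqrt(rowSums(dpos^2)), speed = sqrt(rowSums(dvel^2)))
}

#' Dissociation time and mechanism from the velocity plateau
#'
#' Finds the first time at which the fragment relative speed is flat
#' (varies by less than `plateau_tol` over a sliding window of `window` fs)
#' while the fragment separation is increasing — the operational definition
#' of "dissociation complete". The mechanism is `"direct"` if this happens
#' before `cutoff` fs and `"indirect"` otherwise; trajectories with no such
#' plateau are `"undissociated"`.
#'
#' @param traj An `rp_trajectory`.
#' @param fragments A [fragment_definition()] or list with `a`, `b`.
#' @param plateau_tol Allowed speed variation across the window,
#'   angstrom/fs.
#' @param window Window length, fs.
#' @param cutoff Direct/indirect boundary, fs.
#' @return A list with `time_fs` (`NA` if undissociated) and `mechanism`
#'   (`"direct"`, `"indirect"` or `"undissociated"`).
#' @export
dissociation_time <- function(traj, fragments, plateau_tol = 1e-4,
                              window = 10, cutoff = 75) {
  series <- .trajectory_fragment_series(traj, fragments)
  n <- length(traj$time_fs)
  w <- max(2L, as.integer(round(window / traj$dt_fs)))
  if (n < w) {
    rlang::abort(sprintf("trajectory has %d frames; plateau window needs %d",
                         n, w), class = "rpdyn_state_error")
  }
  v <- series$speed
  d <- series$separation
  for (start in seq_len(n - w + 1L)) {
    win <- start:(start + w - 1L)
    if (max(v[win]) - min(v[win]) < plateau_tol && d[win[w]] > d[win[1L]]) {
      t0 <- traj$time_fs[start]
      return(list(time_fs = t0,
                  mechanism = if (t0 > cutoff) "indirect" else "direct"))
    }
  }
  list(time_fs = NA_real_, mechanism = "undissociated")
}

#' Boltzmann population ratio of two isomers
#'
#' \eqn{\exp(-\Delta E / k_B T)}: the equilibrium concentration ratio of an
#' isomer lying `delta_e` above the most stable form.
#'
#' @param delta_e Energy difference, eV.
#' @param temperature Temperature, K.
#' @return Dimensionless ratio.
#' @examples
#' boltzmann_ratio(0.38, 300) # ~4e-7: a 0.38 eV gap is "roughly 1:10^-6"
#' @export
boltzmann_ratio <- function(delta_e, temperature) {
  stopifnot(temperature > 0)
  kb_ev <- unit_system()$kb * unit_system()$hartree_ev # eV/K
  exp(-delta_e / (kb_ev * temperature))
}

#' Per-trajectory product records
#'
#' Computes, for every trajectory of a set, the electron binding energy
#' carried from detachment, the fragment kinetic-energy release at the
#' final frame, the final centroid dihedral and its cis/trans channel, and
#' the dissociation time and mechanism. This is the table behind the
#' coincidence spectrum and the product-branching summary.
#'
#' @param trajectories An `rp_trajectory_set` (or list of `rp_trajectory`).
#' @param fragments A [fragment_definition()] or list with `a`, `b`.
#' @param dihedral Four atom indices `c(i, j, k, l)`, or `NULL` to skip
#'   torsional analysis (channel then reflects dissociation status only).
#' @inheritParams dissociation_time
#' @return A tibble with one row per trajectory: `id`, `e_b`, `e_k`,
#'   `dihedral`, `channel`, `t_diss`, `mechanism`, `status` (columns in
#'   eV, degrees in (-90, 270], fs).
#' @export
analyze_products <- function(trajectories, fragments, dihedral = NULL,
                             plateau_tol = 1e-4, window = 10, cutoff = 75) {
  trajs <- if (inherits(trajectories, "rp_trajectory_set")) {
    trajectories$trajectories
  } else trajectories
  fragments <- .as_fragments(fragments)
  rows <- purrr::imap(trajs, function(traj, idx) {
    vel <- centroid_velocities(traj$final)
    ek <- relative_kinetic_energy(vel, traj$masses_amu, fragments)
    phi <- NA_real_
    if (!is.null(dihedral)) {
      geom <- centroid(traj$final)
      phi <- report_dihedral(
        dihedral_angle(geom, dihedral[1], dihedral[2], dihedral[3],
                       dihedral[4]))
    }
    dt_info <- dissociation_time(traj, fragments, plateau_tol = plateau_tol,
                                 window = window, cutoff = cutoff)
    channel <- if (dt_info$mechanism == "undissociated") "undissociated"
               else if (is.null(dihedral)) NA_character_
               else classify_channel(phi)
    tibble::tibble(
      id = if (is.na(traj$id)) idx else traj$id,
      e_b = traj$e_b, e_k = ek, dihedral = phi, channel = channel,
      t_diss = dt_info$time_fs, mechanism = dt_info$mechanism,
      status = traj$status
    )
  })
  dplyr::bind_rows(rows)
}
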