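# The ring-polymer state: positions and momenta of all beads of all atoms.
# Internally positions are stored as an ndof x n_beads matrix in bohr
# (row 3*(i-1)+c is Cartesian component c of atom i) and momenta in atomic
# units; accessors convert to angstrom etc.

.flatten_geometry <- function(mat) as.vector(t(mat))

.unflatten_geometry <- function(vec) matrix(vec, ncol = 3L, byrow = TRUE)

#' Ring-polymer bead configuration
#'
#' The state sampled by PIMD and propagated by RPMD: `n_beads` replicas
#' (beads) of an `n_atoms`-atom geometry, joined into a ring polymer, plus
#' conjugate bead momenta. With `n_beads = 1` the object is an ordinary
#' classical phase-space point.
#'
#' Bead momenta follow the Hamiltonian convention in which the kinetic term
#' is \eqn{N (P_i^s)^2 / (2 m_i)}, i.e. the fictitious bead mass is
#' \eqn{m_i/N}; see [ring_polymer_hamiltonian()].
#'
#' @param positions Either an `n_atoms x 3` matrix (replicated over beads)
#'   or an `n_atoms x n_beads x 3` array, in angstrom (or bohr with
#'   `units = "au"`).
#' @param masses Atomic masses, amu (or electron masses with `units = "au"`).
#' @param momenta Optional, same shape options as `positions`; atomic units
#'   only (momenta have no natural interface unit; they are usually drawn
#'   by [initialize_thermal()]). Default zero.
#' @param labels Per-atom element labels; defaults to `"X1"`, `"X2"`, ...
#' @param n_beads Bead count `N`; required when `positions` is a matrix.
#' @param units `"real"` (angstrom/amu) or `"au"`.
#' @return An object of class `bead_configuration`.
#' @examples
#' cfg <- bead_configuration(matrix(0, 1, 3), masses = 1, n_beads = 4)
#' centroid(cfg)
#' @export
bead_configuration <- function(positions, masses, momenta = NULL,
                               labels = NULL, n_beads = NULL,
                               units = c("real", "au")) {
  units <- match.arg(units)
  as_bead_matrix <- function(x, n_beads) {
    if (is.matrix(x)) {
      stopifnot(ncol(x) == 3L)
      matrix(.flatten_geometry(x), nrow = 3L * nrow(x), ncol = n_beads)
    } else if (is.array(x) && length(dim(x)) == 3L) {
      stopifnot(dim(x)[3] == 3L)
      n_atoms <- dim(x)[1]
      out <- matrix(0, 3L * n_atoms, dim(x)[2])
      for (i in seq_len(n_atoms)) {
        out[3L * (i - 1L) + 1:3, ] <- t(x[i, , ])
      }
      out
    } else {
      rlang::abort("positions/momenta must be n_atoms x 3 or n_atoms x n_beads x 3",
                   class = "rpdyn_state_error")
    }
  }
  if (is.matrix(positions)) {
    if (is.null(n_beads)) {
      rlang::abort("`n_beads` is required when positions is a matrix",
                   class = "rpdyn_state_error")
    }
  } else {
    n_beads <- dim(positions)[2]
  }
  stopifnot(n_beads >= 1)
  pos <- as_bead_matrix(positions, n_beads)
  n_atoms <- nrow(pos) %/% 3L
  stopifnot(length(masses) == n_atoms, all(masses > 0), all(is.finite(pos)))
  if (is.null(momenta)) {
    mom <- matrix(0, nrow(pos), ncol(pos))
  } else {
    mom <- as_bead_matrix(momenta, n_beads)
    stopifnot(identical(dim(mom), dim(pos)))
  }
  if (is.null(labels)) labels <- paste0("X", seq_len(n_atoms))
  stopifnot(length(labels) == n_atoms)
  if (units == "real") {
    pos <- to_au(pos, "length")
    masses <- to_au(masses, "mass")
  }
  structure(
    list(
      n_atoms = n_atoms, n_beads = as.integer(n_beads),
      masses = as.numeric(masses), labels = as.character(labels),
      positions = pos, momenta = mom
    ),
    class = "bead_configuration"
  )
}

# masses expanded to one entry per Cartesian degree of freedom (internal units)
.dof_masses <- function(cfg) rep(cfg$masses, each = 3L)

#' @export
print.bead_configuration <- function(x, ...) {
  cat(sprintf("<bead_configuration> %d atom(s) x %d bead(s) [%s]\n",
              x$n_atoms, x$n_beads, paste(x$labels, collapse = " ")))
  invisible(x)
}

#' Bead positions as an array
#'
#' @param cfg A [bead_configuration()].
#' @param units `"angstrom"` or `"au"`.
#' @return An `n_atoms x n_beads x 3` array.
#' @export
bead_positions <- function(cfg, units = c("angstrom", "au")) {
  units <- match.arg(units)
  pos <- cfg$positions
  if (units == "angstrom") pos <- from_au(pos, "length")
  out <- array(0, c(cfg$n_atoms, cfg$n_beads, 3L))
  for (i in seq_len(cfg$n_atoms)) {
    out[i, , ] <- t(pos[3L * (i - 1L) + 1:3, , drop = FALSE])
  }
  out
}

#' Centroid (bead-averaged) positions
#'
#' The arithmetic mean over beads, per atom and Cartesian component — the
#' "classical-like" coordinate of the ring polymer. With one bead it returns
#' the geometry unchanged.
#'
#' @inheritParams bead_positions
#' @return An `n_atoms x 3` matrix.
#' @export
centroid <- function(cfg, units = c("angstrom", "au")) {
  units <- match.arg(units)
  ctr <- rowMeans(cfg$positions)
  if (units == "angstrom") ctr <- from_au(ctr, "length")
  .unflatten_geometry(ctr)
}

#' Centroid velocities
#'
#' Under the bead-mass convention of [ring_polymer_hamiltonian()] the bead
#' velocity is \eqn{N P_i^s / m_i}, so the centroid velocity of atom `i` is
#' `N * mean_s(P_i^s) / m_i`. These are the velocities used for fragment
#' kinetic-energy release.
#'
#' @param cfg A [bead_configuration()].
#' @param units `"angstrom_fs"` or `"au"`.
#' @return An `n_atoms x 3` matrix of velocities.
#' @export
centroid_velocities <- function(cfg, units = c("angstrom_fs", "au")) {
  units <- match.arg(units)
  v <- cfg$n_beads * rowMeans(cfg$momenta) / .dof_masses(cfg)
  if (units == "angstrom_fs") v <- from_au(v, "velocity")
  .unflatten_geometry(v)
}

#' Ring-polymer spring energy
#'
#' The harmonic inter-bead term of the ring-polymer Hamiltonian,
#' \deqn{\sum_i \sum_{s=1}^{N} \frac{m_i N}{2 \beta^2 \hbar^2}
#'       \left| Q_i^s - Q_i^{s-1} \right|^2,}
#' with cyclic indexing (\eqn{Q^0 \equiv Q^N}). Zero for a single bead and
#' for coincident beads.
#'
#' @param cfg A [bead_configuration()].
#' @param thermo A [thermo_context()].
#' @return Spring energy in hartree (nonnegative scalar).
#' @export
spring_energy <- function(cfg, thermo) {
  if (cfg$n_beads == 1L) return(0)
  dq <- cfg$positions - cfg$positions[, c(cfg$n_beads, seq_len(cfg$n_beads - 1L)),
                                      drop = FALSE]
  coef <- .dof_masses(cfg) * cfg$n_beads / (2 * thermo$beta^2) # hbar = 1
  sum(coef * rowSums(dq^2))
}

# spring energy from a raw ndof x n_beads position matrix (internal units)
.spring_energy_mat <- function(pos, dof_masses, n_beads, beta) {
  if (n_beads == 1L) return(0)
  dq <- pos - pos[, c(n_beads, seq_len(n_beads - 1L)), drop = FALSE]
  sum((dof_masses * n_beads / (2 * beta^2)) * rowSums(dq^2))
}

# gradient of spring_energy wrt positions, ndof x n_beads (internal units)
.spring_gradient <- function(pos, dof_masses, n_beads, beta) {
  if (n_beads == 1L) return(matrix(0, nrow(pos), 1L))
  prev <- pos[, c(n_beads, seq_len(n_beads - 1L)), drop = FALSE]
  nxt <- pos[, c(seq(2L, n_beads), 1L), drop = FALSE]
  (dof_masses * n_beads / beta^2) * (2 * pos - prev - nxt)
}

#' Bead kinetic energy
#'
#' \eqn{\sum_{i,s} N (P_i^s)^2 / (2 m_i)}: the kinetic term of the
#' ring-polymer Hamiltonian with fictitious bead mass \eqn{m_i/N}.
#'
#' @inheritParams spring_energy
#' @return Kinetic energy in hartree.
#' @export
bead_kinetic_energy <- function(cfg) {
  sum(cfg$n_beads * cfg$momenta^2 / (2 * .dof_masses(cfg)))
}

#' Ring-polymer Hamiltonian
#'
#' The classical-isomorphism Hamiltonian
#' \deqn{H_N(P, Q) = \sum_{i,s} \frac{(P_i^s)^2}{2 m_i / N}
#'   + \sum_{i,s} \frac{m_i N}{2 \beta^2 \hbar^2} (Q_i^s - Q_i^{s-1})^2
#'   + \frac{1}{N} \sum_s V(Q^s),}
#' whose classical Boltzmann distribution at inverse temperature
#' \eqn{\beta} reproduces quantum position statistics. With `n_beads = 1`
#' it reduces to the classical Hamiltonian \eqn{p^2/2m + V(q)} exactly.
#' It is the conserved quantity of thermostat-free RPMD propagation.
#'
#' @inheritParams spring_energy
#' @param pes A [potential_surface()] supplying `V`.
#' @return Total energy in hartree.
#' @export
ring_polymer_hamiltonian <- function(cfg, thermo, pes) {
  v <- surface_energy(pes, cfg$positions)
  bead_kinetic_energy(cfg) + spring_energy(cfg, thermo) + mean(v)
}

#' Decomposed ring-polymer Hamiltonian
#'
#' @inheritParams ring_polymer_hamiltonian
#' @return A one-row tibble with columns `kinetic`, `spring`, `potential`
#'   and `total` (hartree).
#' @export
hamiltonian_components <- function(cfg, thermo, pes) {
  kin <- bead_kinetic_energy(cfg)
  spr <- spring_energy(cfg, thermo)
  pot <- mean(surface_energy(pes, cfg$positions))
  tibble::tibble(kinetic = kin, spring = spr, potential = pot,
                 total = kin + spr + pot)
}
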