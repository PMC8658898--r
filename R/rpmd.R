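# Vertical detachment and thermostat-free ring-polymer dynamics on the
# neutral surface. A detachment event carries a sampled anion-state bead
# configuration over unchanged (positions and momenta); propagation is
# plain velocity Verlet under the ring-polymer Hamiltonian, which that
# dynamics conserves.

#' Vertical electron detachment of sampled configurations
#'
#' Switches selected ensemble members from the anionic to the neutral
#' surface without touching nuclear positions or momenta (the
#' Franck-Condon / vertical approximation), recording for each event the
#' electron binding energy \eqn{E_b = V_n - V_a} of the detachment
#' geometry (bead-averaged).
#'
#' @param ensemble An `rp_ensemble` sampled on the anion surface.
#' @param pair A [surface_pair()].
#' @param selection Indices of ensemble members to detach; default all.
#' @return A list of class `detachment_events`; each event has fields
#'   `index`, `positions`, `momenta` (identical to the source sample) and
#'   `e_b` (eV).
#' @export
detach <- function(ensemble, pair, selection = NULL) {
  stopifnot(inherits(ensemble, "rp_ensemble"), inherits(pair, "surface_pair"))
  if (is.null(selection)) selection <- seq_along(ensemble$samples)
  if (length(selection) == 0L) {
    rlang::abort("empty detachment selection", class = "rpdyn_state_error")
  }
  stopifnot(all(selection >= 1), all(selection <= length(ensemble$samples)))
  events <- lapply(selection, function(i) {
    s <- ensemble$samples[[i]]
    eb <- mean(surface_energy(pair$neutral, s$positions) -
                 surface_energy(pair$anion, s$positions))
    list(index = i, positions = s$positions, momenta = s$momenta,
         e_b = from_au(eb, "energy"))
  })
  structure(
    list(events = events, n_atoms = ensemble$n_atoms,
         n_beads = ensemble$n_beads, masses = ensemble$masses,
         labels = ensemble$labels, thermo = ensemble$thermo,
         provenance = ensemble$provenance),
    class = "detachment_events"
  )
}

#' @export
print.detachment_events <- function(x, ...) {
  cat(sprintf("<detachment_events> %d event(s), E_b in [%.3f, %.3f] eV\n",
              length(x$events),
              min(vapply(x$events, `[[`, 0, "e_b")),
              max(vapply(x$events, `[[`, 0, "e_b"))))
  invisible(x)
}

#' @export
length.detachment_events <- function(x) length(x$events)

#' Fragment-separation stop rule
#'
#' Terminates a trajectory once the centroid center-of-mass distance
#' between the two fragments exceeds `r_diss` for `sustain` consecutive
#' steps.
#'
#' @param fragments List with integer index vectors `a` and `b`.
#' @param r_diss Separation threshold, angstrom.
#' @param sustain Consecutive steps the threshold must hold.
#' @return A stop-rule object.
#' @export
stop_rule_distance <- function(fragments, r_diss = 8, sustain = 50L) {
  stopifnot(length(fragments$a) >= 1, length(fragments$b) >= 1,
            length(intersect(fragments$a, fragments$b)) == 0L, r_diss > 0)
  structure(list(type = "distance", fragments = fragments,
                 r_diss = r_diss, sustain = as.integer(sustain)),
            class = "rp_stop_rule")
}

#' Run-to-completion stop rule (no early termination)
#' @return A stop-rule object.
#' @export
stop_rule_none <- function() {
  structure(list(type = "none"), class = "rp_stop_rule")
}

# mass-weighted fragment COM separation from an ndof x n_beads position
# matrix (internal units)
.fragment_separation <- function(pos, masses, fragments) {
  ctr <- rowMeans(pos)
  com <- function(idx) {
    w <- masses[idx] / sum(masses[idx])
    acc <- c(0, 0, 0)
    for (t in seq_along(idx)) {
      acc <- acc + w[t] * ctr[.rows3(idx[t])]
    }
    acc
  }
  sqrt(sum((com(fragments$a) - com(fragments$b))^2))
}

#' Microcanonical (NVE) ring-polymer propagation
#'
#' Velocity-Verlet propagation of one detachment event on the neutral
#' surface, without a thermostat: real-time RPMD. The ring-polymer
#' Hamiltonian is recorded every frame as a conservation diagnostic.
#' Integration failures are reported as an `"error"` terminal status on the
#' trajectory (not an exception), so ensembles always complete.
#'
#' @param event One element of [detach()]'s `events`, or a
#'   [bead_configuration()].
#' @param pes The neutral-state [potential_surface()].
#' @param thermo A [thermo_context()] (sets the bead-spring stiffness; use
#'   the sampling temperature).
#' @param masses,labels Atomic masses (amu) / labels, required when `event`
#'   is a bare configuration list; taken from the configuration otherwise.
#' @param dt Time step, fs.
#' @param max_steps Maximum number of steps.
#' @param stop_rule A [stop_rule_distance()] or [stop_rule_none()].
#' @param record_stride Record every `record_stride`-th frame.
#' @param mode A [force_mode()] or mode string.
#' @param store_beads Keep full bead positions per recorded frame (memory
#'   heavy; default centroid-only).
#' @param time_units `"fs"` or `"au"` for `dt`.
#' @return An object of class `rp_trajectory` with the uniform time grid
#'   (fs), per-frame centroid positions (angstrom) and velocities
#'   (angstrom/fs), the conserved Hamiltonian (eV), terminal status
#'   (`"dissociated"`, `"max_time"` or `"error"`) and the final bead
#'   configuration.
#' @export
propagate_nve <- function(event, pes, thermo, masses = NULL, labels = NULL,
                          dt = 0.3, max_steps = 500L,
                          stop_rule = stop_rule_none(), record_stride = 1L,
                          mode = "exact_beads", store_beads = FALSE,
                          time_units = c("fs", "au")) {
  time_units <- match.arg(time_units)
  mode <- .as_force_mode(mode)
  if (inherits(event, "bead_configuration")) {
    cfg <- event
    ev_index <- NA_integer_
    e_b <- NA_real_
  } else {
    stopifnot(!is.null(masses))
    cfg <- structure(
      list(n_atoms = length(masses), n_beads = ncol(event$positions),
           masses = to_au(masses, "mass"),
           labels = labels %||% paste0("X", seq_along(masses)),
           positions = event$positions, momenta = event$momenta),
      class = "bead_configuration")
    ev_index <- event$index
    e_b <- event$e_b
  }
  dt_au <- .dt_au(dt, time_units)
  dt_fs <- if (time_units == "fs") dt else from_au(dt, "time")
  ndof <- 3L * cfg$n_atoms
  n_beads <- cfg$n_beads
  dofm <- .dof_masses(cfg)
  beta <- thermo$beta
  cache <- new.env(parent = emptyenv())
  pos <- cfg$positions
  mom <- cfg$momenta

  n_frames_max <- max_steps %/% record_stride + 1L
  t_grid <- numeric(n_frames_max)
  ctr_pos <- matrix(NA_real_, n_frames_max, ndof)
  ctr_vel <- matrix(NA_real_, n_frames_max, ndof)
  ham <- numeric(n_frames_max)
  bead_frames <- if (store_beads) vector("list", n_frames_max) else NULL

  hamiltonian_of <- function(pos, mom) {
    sum(n_beads * mom^2 / (2 * dofm)) +
      .spring_energy_mat(pos, dofm, n_beads, beta) +
      mean(surface_energy(pes, pos))
  }
  record <- function(i, step, pos, mom) {
    t_grid[i] <<- step * dt_fs
    ctr_pos[i, ] <<- rowMeans(pos)
    ctr_vel[i, ] <<- n_beads * rowMeans(mom) / dofm
    ham[i] <<- hamiltonian_of(pos, mom)
    if (store_beads) bead_frames[[i]] <<- pos
  }

  status <- "max_time"
  i_frame <- 1L
  record(1L, 0L, pos, mom)
  sustain_count <- 0L
  n_done <- 0L
  f <- tryCatch(
    -.spring_gradient(pos, dofm, n_beads, beta) -
      .bead_gradients(pes, pos, mode, cache) / n_beads,
    error = function(e) NULL)
  if (is.null(f)) status <- "error"
  if (status != "error") {
    for (step in seq_len(max_steps)) {
      mom <- mom + f * dt_au / 2
      pos <- pos + (mom * n_beads / dofm) * dt_au
      if (!all(is.finite(pos))) {
        status <- "error"
        break
      }
      f <- -.spring_gradient(pos, dofm, n_beads, beta) -
        .bead_gradients(pes, pos, mode, cache) / n_beads
      mom <- mom + f * dt_au / 2
      n_done <- step
      if (step %% record_stride == 0L) {
        i_frame <- i_frame + 1L
        record(i_frame, step, pos, mom)
      }
      if (stop_rule$type == "distance") {
        sep <- .fragment_separation(pos, cfg$masses, stop_rule$fragments)
        if (sep > to_au(stop_rule$r_diss, "length")) {
          sustain_count <- sustain_count + 1L
          if (sustain_count >= stop_rule$sustain) {
            status <- "dissociated"
            break
          }
        } else {
          sustain_count <- 0L
        }
      }
    }
  }
  keep <- seq_len(i_frame)
  final <- cfg
  final$positions <- pos
  final$momenta <- mom
  u <- unit_system()
  structure(
    list(
      id = ev_index, e_b = e_b,
      time_fs = t_grid[keep],
      centroid_positions = from_au(ctr_pos[keep, , drop = FALSE], "length"),
      centroid_velocities = from_au(ctr_vel[keep, , drop = FALSE], "velocity"),
      hamiltonian_ev = from_au(ham[keep], "energy"),
      status = status, n_steps = n_done, dt_fs = dt_fs * record_stride,
      final = final, masses_amu = from_au(cfg$masses, "mass"),
      labels = cfg$labels,
      bead_frames = if (store_beads) bead_frames[keep] else NULL
    ),
    class = "rp_trajectory"
  )
}

#' @export
print.rp_trajectory <- function(x, ...) {
  cat(sprintf("<rp_trajectory> %d frame(s), %.1f fs, status: %s\n",
              length(x$time_fs), max(x$time_fs), x$status))
  invisible(x)
}

#' Propagate an ensemble of detachment events
#'
#' Each event is propagated independently (results do not depend on
#' execution order). Momenta are the PIMD momenta carried over by default;
#' optionally they can be redrawn thermally per trajectory using a stream
#' seeded as `seed + event index`, keeping results reproducible and
#' order-independent.
#'
#' @param events A [detach()] result.
#' @param pes Neutral-state [potential_surface()].
#' @param thermo A [thermo_context()]; defaults to the sampling context
#'   stored in `events`.
#' @param resample_momenta Draw fresh Maxwell momenta per trajectory.
#' @param seed Base seed for momentum resampling.
#' @inheritParams propagate_nve
#' @return An object of class `rp_trajectory_set` (list of
#'   `rp_trajectory` plus shared metadata).
#' @export
run_ensemble <- function(events, pes, thermo = NULL, dt = 0.3,
                         max_steps = 500L, stop_rule = stop_rule_none(),
                         record_stride = 1L, mode = "exact_beads",
                         store_beads = FALSE, resample_momenta = FALSE,
                         seed = 1L, time_units = c("fs", "au")) {
  stopifnot(inherits(events, "detachment_events"), length(events$events) >= 1)
  time_units <- match.arg(time_units)
  if (is.null(thermo)) thermo <- events$thermo
  masses_amu <- from_au(events$masses, "mass")
  mtilde <- rep(events$masses, each = 3L) / events$n_beads
  trajs <- lapply(events$events, function(ev) {
    if (resample_momenta) {
      set.seed(seed + ev$index)
      ev$momenta <- matrix(stats::rnorm(length(ev$momenta)),
                           nrow(ev$momenta)) * sqrt(mtilde * thermo$kT)
    }
    propagate_nve(ev, pes, thermo, masses = masses_amu,
                  labels = events$labels, dt = dt, max_steps = max_steps,
                  stop_rule = stop_rule, record_stride = record_stride,
                  mode = mode, store_beads = store_beads,
                  time_units = time_units)
  })
  structure(
    list(trajectories = trajs, labels = events$labels,
         masses_amu = masses_amu, thermo = thermo,
         provenance = c(events$provenance, list(dt = dt, seed = seed))),
    class = "rp_trajectory_set"
  )
}

#' @export
print.rp_trajectory_set <- function(x, ...) {
  st <- table(vapply(x$trajectories, `[[`, "", "status"))
  cat(sprintf("<rp_trajectory_set> %d trajectories (%s)\n",
              length(x$trajectories),
              paste(names(st), st, sep = ": ", collapse = ", ")))
  invisible(x)
}

#' @export
length.rp_trajectory_set <- function(x) length(x$trajectories)
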