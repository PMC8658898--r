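# Thermostatted path-integral molecular dynamics: samples the classical
# Boltzmann distribution of the ring-polymer Hamiltonian, which reproduces
# the quantum thermal position density of the nuclei. With n_beads = 1 the
# same machinery is plain classical MD.

#' PIMD sampler configuration
#'
#' Collects every knob of the thermal sampling stage. The defaults are the
#' production conditions of a molecular run: 300 K, 32 beads, a 0.3 fs time
#' step and 1e5 steps, with the centroid Taylor force approximation.
#'
#' @param temperature Temperature in K (or give `beta`).
#' @param beta Inverse temperature, 1/hartree (model-unit studies).
#' @param n_beads Bead count N; 1 gives classical MD (the spring term
#'   vanishes identically).
#' @param dt Time step, fs (or internal units with `time_units = "au"`).
#' @param n_steps Total number of steps.
#' @param burn_in Steps discarded before recording; default 20% of
#'   `n_steps`.
#' @param sample_stride Record every `sample_stride`-th post-burn-in state.
#' @param seed Integer seed; every stochastic choice of the sampler flows
#'   from it.
#' @param force_mode A [force_mode()] or mode string.
#' @param m_links Nose-Hoover chain length per DOF.
#' @param tau_steps Thermostat time constant in units of `dt`.
#' @param jitter Initial bead spread around the template, angstrom.
#' @param time_units `"fs"` or `"au"` for `dt`.
#' @param diag_stride Steps between diagnostic records.
#' @return An object of class `sampler_config`.
#' @export
sampler_config <- function(temperature = 300, beta = NULL, n_beads = 32L,
                           dt = 0.3, n_steps = 1e5L, burn_in = NULL,
                           sample_stride = 10L, seed = 1L,
                           force_mode = "centroid_taylor",
                           m_links = 4L, tau_steps = 20, jitter = 0.05,
                           time_units = c("fs", "au"), diag_stride = 50L) {
  time_units <- match.arg(time_units)
  if (is.null(burn_in)) burn_in <- floor(0.2 * n_steps)
  stopifnot(dt > 0, n_steps > burn_in, burn_in >= 0, sample_stride >= 1,
            n_beads >= 1, jitter >= 0)
  thermo <- if (!is.null(beta)) thermo_context(beta = beta)
            else thermo_context(temperature = temperature)
  structure(
    list(thermo = thermo, n_beads = as.integer(n_beads), dt = dt,
         n_steps = as.integer(n_steps), burn_in = as.integer(burn_in),
         sample_stride = as.integer(sample_stride), seed = as.integer(seed),
         force_mode = .as_force_mode(force_mode), m_links = as.integer(m_links),
         tau_steps = tau_steps, jitter = jitter, time_units = time_units,
         diag_stride = as.integer(diag_stride)),
    class = "sampler_config"
  )
}

.dt_au <- function(dt, time_units) {
  if (time_units == "fs") to_au(dt, "time") else dt
}

#' Thermal initialization of a bead configuration
#'
#' Beads are jittered around the template geometry with an isotropic
#' Gaussian of width `jitter`, and bead momenta are drawn from the Maxwell
#' distribution consistent with the ring-polymer kinetic-energy convention
#' (fictitious bead mass \eqn{m_i/N}), so each bead DOF carries
#' \eqn{k_B T/2} of kinetic energy on average. Fully reproducible under a
#' fixed seed.
#'
#' @param template A [bead_configuration()] giving geometry, masses and
#'   bead count (positions may be bead-replicated).
#' @param thermo A [thermo_context()].
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param jitter Bead position spread, angstrom.
#' @return A [bead_configuration()].
#' @export
initialize_thermal <- function(template, thermo, seed = NULL, jitter = 0.05) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(template$positions)
  pos <- template$positions +
    matrix(stats::rnorm(n, sd = max(to_au(jitter, "length"), 1e-300)),
           nrow(template$positions))
  mtilde <- .dof_masses(template) / template$n_beads
  mom <- matrix(stats::rnorm(n), nrow(template$positions)) *
    sqrt(mtilde * thermo$kT)
  out <- template
  out$positions <- pos
  out$momenta <- mom
  out
}

#' One thermostatted velocity-Verlet step
#'
#' Advances a bead configuration by one time step `dt` under the
#' ring-polymer equations of motion: half-step Nose-Hoover chain, velocity
#' Verlet under the bead spring + potential forces, half-step chain. With
#' `chain = NULL` the thermostat is skipped, giving plain (time-reversible,
#' symplectic) velocity Verlet.
#'
#' @param cfg A [bead_configuration()].
#' @param chain An [nhc_chain()] or `NULL`.
#' @param pes A [potential_surface()].
#' @param thermo A [thermo_context()] (sets the spring stiffness).
#' @param dt Time step, fs.
#' @param mode A [force_mode()] or mode string.
#' @return A list with elements `config` and `chain`.
#' @export
nhc_velocity_verlet_step <- function(cfg, chain, pes, thermo, dt,
                                     mode = "exact_beads") {
  mode <- .as_force_mode(mode)
  dt <- to_au(dt, "time")
  dofm <- .dof_masses(cfg)
  n_beads <- cfg$n_beads
  mtilde_vec <- rep(dofm / n_beads, n_beads)
  pos <- cfg$positions
  mom <- cfg$momenta
  force <- function(p) {
    -.spring_gradient(p, dofm, n_beads, thermo$beta) -
      .bead_gradients(pes, p, mode) / n_beads
  }
  if (!is.null(chain)) {
    r <- .nhc_half_step(as.vector(mom), mtilde_vec, chain, dt / 2)
    mom <- matrix(r$p, nrow(mom)); chain <- r$chain
  }
  mom <- mom + force(pos) * dt / 2
  pos <- pos + (mom * n_beads / dofm) * dt
  mom <- mom + force(pos) * dt / 2
  if (!is.null(chain)) {
    r <- .nhc_half_step(as.vector(mom), mtilde_vec, chain, dt / 2)
    mom <- matrix(r$p, nrow(mom)); chain <- r$chain
  }
  out <- cfg
  out$positions <- pos
  out$momenta <- mom
  list(config = out, chain = chain)
}

#' Sample the quantum thermal density by PIMD
#'
#' Runs massive-NHC thermostatted dynamics of the ring polymer on `pes`,
#' discards `burn_in` steps and records every `sample_stride`-th state.
#' The recorded ensemble of bead configurations represents the quantum
#' Boltzmann position density of the nuclei on that surface (classical
#' Boltzmann for `n_beads = 1`), and is the initial-condition reservoir for
#' vertical detachment.
#'
#' @param template A [bead_configuration()] (starting geometry, masses,
#'   labels; its bead count is overridden by `config$n_beads`), or a
#'   [surface_pair()], in which case its template geometry and masses are
#'   used and `pes` defaults to the anion surface.
#' @param pes A [potential_surface()] to sample on.
#' @param config A [sampler_config()].
#' @return An object of class `rp_ensemble`: the recorded samples plus a
#'   diagnostics tibble (step, instantaneous temperature, Hamiltonian
#'   components) and provenance (seed, configuration hash).
#' @export
pimd_sample <- function(template, pes = NULL, config = sampler_config()) {
  if (inherits(template, "surface_pair")) {
    pair <- template
    if (is.null(pair$template) || is.null(pair$masses)) {
      rlang::abort("surface_pair carries no template geometry/masses",
                   class = "rpdyn_state_error")
    }
    if (is.null(pes)) pes <- pair$anion
    template <- bead_configuration(pair$template, masses = pair$masses,
                                   labels = pair$labels,
                                   n_beads = config$n_beads)
  }
  stopifnot(inherits(template, "bead_configuration"),
            inherits(config, "sampler_config"))
  if (template$n_beads != config$n_beads) {
    template <- bead_configuration(
      centroid(template, units = "angstrom"),
      masses = from_au(template$masses, "mass"),
      labels = template$labels, n_beads = config$n_beads)
  }
  thermo <- config$thermo
  mode <- config$force_mode
  if (mode$mode == "centroid_taylor" && thermo$temperature < 200) {
    rlang::warn(paste0(
      "centroid Taylor forces requested at T = ",
      signif(thermo$temperature, 4),
      " K; the expansion is only reliable above ~200 K"),
      class = "rpdyn_low_temperature_warning")
  }
  dt <- .dt_au(config$dt, config$time_units)
  cfg <- initialize_thermal(template, thermo, seed = config$seed,
                            jitter = config$jitter)
  ndof <- 3L * cfg$n_atoms
  n_beads <- cfg$n_beads
  dofm <- .dof_masses(cfg)
  mtilde_vec <- rep(dofm / n_beads, n_beads)
  chain <- nhc_chain(ndof, n_beads, kT = thermo$kT,
                     tau = config$tau_steps * dt, m_links = config$m_links)
  cache <- new.env(parent = emptyenv())
  pos <- cfg$positions
  mom <- cfg$momenta
  beta <- thermo$beta
  kb <- unit_system()$kb
  pot_force <- function(p) -.bead_gradients(pes, p, mode, cache) / n_beads

  n_rec <- (config$n_steps - config$burn_in) %/% config$sample_stride
  samples <- vector("list", n_rec)
  n_diag <- config$n_steps %/% config$diag_stride
  diag <- matrix(NA_real_, n_diag, 5L,
                 dimnames = list(NULL, c("step", "temperature", "kinetic",
                                         "spring", "potential")))
  i_rec <- 0L
  i_diag <- 0L
  f <- pot_force(pos) - .spring_gradient(pos, dofm, n_beads, beta)
  for (step in seq_len(config$n_steps)) {
    r <- .nhc_half_step(as.vector(mom), mtilde_vec, chain, dt / 2)
    mom <- matrix(r$p, ndof)
    chain <- r$chain
    mom <- mom + f * dt / 2
    pos <- pos + (mom * n_beads / dofm) * dt
    if (!all(is.finite(pos))) {
      rlang::abort(sprintf("PIMD integration blew up at step %d", step),
                   class = "rpdyn_integration_error")
    }
    f <- pot_force(pos) - .spring_gradient(pos, dofm, n_beads, beta)
    mom <- mom + f * dt / 2
    r <- .nhc_half_step(as.vector(mom), mtilde_vec, chain, dt / 2)
    mom <- matrix(r$p, ndof)
    chain <- r$chain
    if (step %% config$diag_stride == 0L && i_diag < n_diag) {
      i_diag <- i_diag + 1L
      ke <- sum(n_beads * mom^2 / (2 * dofm))
      diag[i_diag, ] <- c(step, 2 * ke / (ndof * n_beads * kb), ke,
                          .spring_energy_mat(pos, dofm, n_beads, beta),
                          mean(surface_energy(pes, pos)))
    }
    if (step > config$burn_in &&
        (step - config$burn_in) %% config$sample_stride == 0L &&
        i_rec < n_rec) {
      i_rec <- i_rec + 1L
      samples[[i_rec]] <- list(positions = pos, momenta = mom)
    }
  }
  structure(
    list(samples = samples[seq_len(i_rec)], n_atoms = cfg$n_atoms,
         n_beads = n_beads, masses = cfg$masses, labels = cfg$labels,
         thermo = thermo,
         diagnostics = tibble::as_tibble(diag[seq_len(i_diag), , drop = FALSE]),
         provenance = list(seed = config$seed,
                           config_hash = rlang::hash(unclass(config)),
                           surface = pes$name)),
    class = "rp_ensemble"
  )
}

#' @export
print.rp_ensemble <- function(x, ...) {
  cat(sprintf(
    "<rp_ensemble> %d sample(s) of %d atom(s) x %d bead(s) at T = %.4g K\n",
    length(x$samples), x$n_atoms, x$n_beads, x$thermo$temperature))
  invisible(x)
}

#' @export
length.rp_ensemble <- function(x) length(x$samples)

#' Extract one ensemble member as a bead configuration
#'
#' @param ensemble An `rp_ensemble`.
#' @param i Sample index.
#' @return A [bead_configuration()].
#' @export
ensemble_configuration <- function(ensemble, i) {
  stopifnot(i >= 1, i <= length(ensemble$samples))
  structure(
    list(n_atoms = ensemble$n_atoms, n_beads = ensemble$n_beads,
         masses = ensemble$masses, labels = ensemble$labels,
         positions = ensemble$samples[[i]]$positions,
         momenta = ensemble$samples[[i]]$momenta),
    class = "bead_configuration"
  )
}

# ndof x (n_samples * n_beads) matrix of all bead columns (internal units)
.ensemble_bead_matrix <- function(ensemble) {
  do.call(cbind, lapply(ensemble$samples, `[[`, "positions"))
}

# ndof x n_samples matrix of centroids (internal units)
.ensemble_centroid_matrix <- function(ensemble) {
  vapply(ensemble$samples, function(s) rowMeans(s$positions),
         numeric(3L * ensemble$n_atoms))
}
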