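# Shared oracles and fixture builders, independent of the code paths they
# check.

# central finite-difference gradient of a surface at a single geometry
fd_gradient <- function(pes, q, h = 1e-6) {
  vapply(seq_along(q), function(d) {
    qp <- q; qm <- q
    qp[d] <- qp[d] + h
    qm[d] <- qm[d] - h
    (surface_energy(pes, qp) - surface_energy(pes, qm)) / (2 * h)
  }, numeric(1))
}

# Exact position covariance of a 1D ring polymer on a harmonic surface:
# the Boltzmann weight exp(-beta * U) with
# U = (1/N) sum_s m w^2 x_s^2 / 2 + sum_s (m N / 2 beta^2) (x_s - x_{s-1})^2
# is Gaussian; covariance = (beta A)^{-1} with A the quadratic-form matrix.
ring_polymer_covariance_1d <- function(m, omega, beta, n_beads) {
  lap <- matrix(0, n_beads, n_beads)
  for (s in seq_len(n_beads)) {
    sm <- if (s == 1L) n_beads else s - 1L
    lap[s, s] <- lap[s, s] + 2
    lap[s, sm] <- lap[s, sm] - 1
    lap[sm, s] <- lap[sm, s] - 1
  }
  if (n_beads == 1L) lap <- matrix(0, 1, 1)
  a <- diag(m * omega^2 / n_beads, n_beads) + (m * n_beads / beta^2) * lap
  solve(beta * a)
}

# quantum harmonic oscillator <x^2> (infinite-bead limit), hbar = 1
qho_msd_quantum <- function(m, omega, beta) {
  1 / (2 * m * omega) / tanh(beta * omega / 2)
}

# torsion via explicit rotation construction: rotate the last atom about
# the j->k axis by a known angle and return the constructed geometry
rotate_about_axis <- function(point, origin, axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  v <- point - origin
  v_rot <- v * cos(th) + c(a[2] * v[3] - a[3] * v[2],
                           a[3] * v[1] - a[1] * v[3],
                           a[1] * v[2] - a[2] * v[1]) * sin(th) +
    a * sum(a * v) * (1 - cos(th))
  origin + v_rot
}

random_rotation_matrix <- function() {
  qr_res <- qr(matrix(stats::rnorm(9), 3))
  q <- qr.Q(qr_res)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# small ready-made bead configuration in internal units
make_config_au <- function(positions, masses, n_beads, momenta = NULL,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bead_configuration(positions, masses = masses, momenta = momenta,
                     n_beads = n_beads, units = "au")
}
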