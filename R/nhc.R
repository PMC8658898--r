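# Massive Nose-Hoover chain thermostat: one independent chain of M links
# coupled to every Cartesian degree of freedom of every bead. Chains are
# stored flattened (ndof * n_beads rows, M columns) so the update is a few
# vectorized sweeps. Integration uses the standard time-reversible
# symmetric splitting (half chain / velocity Verlet / half chain).

#' Massive Nose-Hoover thermostat chains
#'
#' Creates the chain state for a system of `ndof x n_beads` degrees of
#' freedom: each DOF gets its own chain of `m_links` links ("massive"
#' scheme), all initialized at rest. Thermostat masses are
#' \eqn{Q = k_B T \tau^2} for every link.
#'
#' @param ndof Cartesian degrees of freedom per bead (3 x atoms).
#' @param n_beads Bead count.
#' @param kT Target thermal energy per DOF, hartree.
#' @param tau Thermostat time constant, internal time units (a common,
#'   robust choice is 20 time steps).
#' @param m_links Chain length M (>= 1), default 4.
#' @return An object of class `nhc_chain`.
#' @export
nhc_chain <- function(ndof, n_beads, kT, tau, m_links = 4L) {
  stopifnot(ndof >= 1, n_beads >= 1, kT > 0, tau > 0, m_links >= 1)
  k <- ndof * n_beads
  structure(
    list(xi = matrix(0, k, m_links), vxi = matrix(0, k, m_links),
         q = rep(kT * tau^2, m_links), kT = kT,
         m_links = as.integer(m_links), tau = tau),
    class = "nhc_chain"
  )
}

# One reversible half-step (dt2 = dt/2) of the chain acting on momenta.
# p: vector of length ndof*n_beads; mtilde: matching fictitious masses.
# Hot path: works on local copies of the chain state (no repeated list
# mutation) and unpacks the link update into plain vector arithmetic.
.nhc_half_step <- function(p, mtilde, ch, dt2) {
  m <- ch$m_links
  q <- ch$q
  kT <- ch$kT
  vxi <- ch$vxi
  dt4 <- dt2 / 2
  dt8 <- dt4 / 2
  ke2 <- p^2 / mtilde # twice the kinetic energy per DOF
  if (m > 1L) {
    vxi[, m] <- vxi[, m] + (q[m - 1L] * vxi[, m - 1L]^2 - kT) * (dt4 / q[m])
    for (j in (m - 1L):1L) {
      sc <- exp(-dt8 * vxi[, j + 1L])
      g <- if (j == 1L) (ke2 - kT) / q[1L]
           else (q[j - 1L] * vxi[, j - 1L]^2 - kT) / q[j]
      vxi[, j] <- (vxi[, j] * sc + g * dt4) * sc
    }
  } else {
    vxi[, 1L] <- vxi[, 1L] + (ke2 - kT) * (dt4 / q[1L])
  }
  scale <- exp(-dt2 * vxi[, 1L])
  p <- p * scale
  ke2 <- ke2 * scale^2
  ch$xi <- ch$xi + dt2 * vxi
  if (m > 1L) {
    for (j in 1L:(m - 1L)) {
      sc <- exp(-dt8 * vxi[, j + 1L])
      g <- if (j == 1L) (ke2 - kT) / q[1L]
           else (q[j - 1L] * vxi[, j - 1L]^2 - kT) / q[j]
      vxi[, j] <- (vxi[, j] * sc + g * dt4) * sc
    }
    vxi[, m] <- vxi[, m] + (q[m - 1L] * vxi[, m - 1L]^2 - kT) * (dt4 / q[m])
  } else {
    vxi[, 1L] <- vxi[, 1L] + (ke2 - kT) * (dt4 / q[1L])
  }
  ch$vxi <- vxi
  list(p = p, chain = ch)
}
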