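# Analytic molecular model surfaces built from valence coordinates (bonds,
# angles, torsions), with analytic gradients, vectorized over geometry
# columns. These stand in for the on-the-fly electronic structure of a real
# dissociative-photodetachment calculation: a bound anion surface and a
# neutral surface that is repulsive along the dissociation coordinate at the
# anion geometry, so vertical detachment lands in the Franck-Condon region
# of a repulsive wall.

.rows3 <- function(i) 3L * (i - 1L) + 1:3

.cross3 <- function(a, b) {
  rbind(a[2, ] * b[3, ] - a[3, ] * b[2, ],
        a[3, ] * b[1, ] - a[1, ] * b[3, ],
        a[1, ] * b[2, ] - a[2, ] * b[1, ])
}

.dot3 <- function(a, b) colSums(a * b)

.norm3 <- function(a) sqrt(colSums(a^2))

# Each term returns list(energy = length-m vector, grad = ndof x m matrix).

.term_bond_harmonic <- function(q, i, j, r0, k) {
  d <- q[.rows3(j), , drop = FALSE] - q[.rows3(i), , drop = FALSE]
  len <- .norm3(d)
  u <- sweep(d, 2L, len, "/")
  dvdr <- k * (len - r0)
  g <- matrix(0, nrow(q), ncol(q))
  g[.rows3(j), ] <- sweep(u, 2L, dvdr, "*")
  g[.rows3(i), ] <- -g[.rows3(j), , drop = FALSE]
  list(energy = k * (len - r0)^2 / 2, grad = g)
}

.term_bond_repulsive <- function(q, i, j, r0, amp, alpha, e_inf) {
  d <- q[.rows3(j), , drop = FALSE] - q[.rows3(i), , drop = FALSE]
  len <- .norm3(d)
  u <- sweep(d, 2L, len, "/")
  ex <- exp(-alpha * (len - r0))
  dvdr <- -alpha * amp * ex
  g <- matrix(0, nrow(q), ncol(q))
  g[.rows3(j), ] <- sweep(u, 2L, dvdr, "*")
  g[.rows3(i), ] <- -g[.rows3(j), , drop = FALSE]
  list(energy = amp * ex + e_inf, grad = g)
}

.term_angle_harmonic <- function(q, i, j, k, theta0, ka) {
  u <- q[.rows3(i), , drop = FALSE] - q[.rows3(j), , drop = FALSE]
  v <- q[.rows3(k), , drop = FALSE] - q[.rows3(j), , drop = FALSE]
  nu <- .norm3(u); nv <- .norm3(v)
  cth <- pmin(1, pmax(-1, .dot3(u, v) / (nu * nv)))
  th <- acos(cth)
  sth <- sqrt(pmax(1 - cth^2, 1e-14))
  # d(theta)/d(u) = (cth*u/nu^2 - v/(nu*nv)) / sth
  gi <- sweep(sweep(u, 2L, cth / nu^2, "*") - sweep(v, 2L, 1 / (nu * nv), "*"),
              2L, sth, "/")
  gk <- sweep(sweep(v, 2L, cth / nv^2, "*") - sweep(u, 2L, 1 / (nu * nv), "*"),
              2L, sth, "/")
  dvdth <- ka * (th - theta0)
  g <- matrix(0, nrow(q), ncol(q))
  g[.rows3(i), ] <- sweep(gi, 2L, dvdth, "*")
  g[.rows3(k), ] <- sweep(gk, 2L, dvdth, "*")
  g[.rows3(j), ] <- -(g[.rows3(i), , drop = FALSE] + g[.rows3(k), , drop = FALSE])
  list(energy = ka * (th - theta0)^2 / 2, grad = g)
}

# signed torsion phi(i,j,k,l) in radians, plus dphi/dr for all four atoms
.torsion_and_gradient <- function(q, i, j, k, l) {
  b1 <- q[.rows3(j), , drop = FALSE] - q[.rows3(i), , drop = FALSE]
  b2 <- q[.rows3(k), , drop = FALSE] - q[.rows3(j), , drop = FALSE]
  b3 <- q[.rows3(l), , drop = FALSE] - q[.rows3(k), , drop = FALSE]
  m <- .cross3(b1, b2)
  n <- .cross3(b2, b3)
  nb2 <- .norm3(b2)
  phi <- atan2(.dot3(.cross3(m, n), b2) / nb2, .dot3(m, n))
  m2 <- pmax(colSums(m^2), 1e-30)
  n2 <- pmax(colSums(n^2), 1e-30)
  gi <- sweep(m, 2L, -nb2 / m2, "*")
  gl <- sweep(n, 2L, nb2 / n2, "*")
  p <- .dot3(b1, b2) / nb2^2
  s <- .dot3(b3, b2) / nb2^2
  gj <- sweep(gi, 2L, -(1 + p), "*") + sweep(gl, 2L, s, "*")
  gk <- sweep(gi, 2L, p, "*") - sweep(gl, 2L, 1 + s, "*")
  list(phi = phi, gi = gi, gj = gj, gk = gk, gl = gl)
}

# torsional double well V2/2 * (1 - cos 2 phi): minima at phi = 0 (cis) and
# phi = pi (trans), barrier V2 at phi = +-pi/2
.term_torsion_double_well <- function(q, i, j, k, l, v2) {
  tg <- .torsion_and_gradient(q, i, j, k, l)
  dvdphi <- v2 * sin(2 * tg$phi)
  g <- matrix(0, nrow(q), ncol(q))
  g[.rows3(i), ] <- sweep(tg$gi, 2L, dvdphi, "*")
  g[.rows3(j), ] <- sweep(tg$gj, 2L, dvdphi, "*")
  g[.rows3(k), ] <- sweep(tg$gk, 2L, dvdphi, "*")
  g[.rows3(l), ] <- sweep(tg$gl, 2L, dvdphi, "*")
  list(energy = v2 / 2 * (1 - cos(2 * tg$phi)), grad = g)
}

.valence_surface <- function(name, n_atoms, terms, params) {
  evaluate <- function(q) {
    e <- numeric(ncol(q))
    g <- matrix(0, nrow(q), ncol(q))
    for (tm in terms) {
      res <- tm(q)
      e <- e + res$energy
      g <- g + res$grad
    }
    list(energy = e, grad = g)
  }
  potential_surface(
    name = name, ndof = 3L * n_atoms,
    energy = function(q) evaluate(q)$energy,
    gradient = function(q) evaluate(q)$grad,
    hessian = NULL, params = params
  )
}

#' Two-surface toy photodetachment system (pseudo-diatomic)
#'
#' A two-atom model of the anion/neutral pair that drives a dissociative
#' photodetachment: the anionic state binds the bond harmonically,
#' \deqn{V_a(R) = \tfrac12 k (R - R_0)^2,}
#' while the neutral state is purely repulsive along the same coordinate,
#' \deqn{V_n(R) = A e^{-\alpha (R - R_0)} + E_\infty,}
#' so a vertical detachment at the anion minimum lands on a repulsive wall
#' of height \eqn{A} above the dissociation asymptote \eqn{E_\infty}. A
#' classical particle released at rest from \eqn{R_0} therefore acquires a
#' terminal kinetic-energy release of exactly \eqn{A}, and the vertical gap
#' at \eqn{R_0} is \eqn{A + E_\infty}.
#'
#' The defaults mirror the energy scales of a carboxylate-loss
#' photodetachment at 300 K: vertical gap 4.6 eV, kinetic-energy release
#' 0.9 eV, and a light effective mass putting the bound stretch in the
#' quantum regime (\eqn{\beta\hbar\omega \approx 3}).
#'
#' @param k Anion force constant, eV/angstrom^2.
#' @param r0 Anion equilibrium distance, angstrom.
#' @param amp Repulsion amplitude `A`, eV.
#' @param alpha Repulsion range, 1/angstrom.
#' @param e_inf Neutral dissociation asymptote, eV (measured from the anion
#'   minimum).
#' @param offset Additional vertical offset added to the anion surface, eV.
#' @param masses Two atomic masses, amu.
#' @param labels Two element labels (used in XYZ output).
#' @return A [surface_pair()] whose `meta` declares the two fragments and
#'   the template geometry (bond along x, centered at the origin).
#' @export
toy_photodetachment_system <- function(k = 1.4, r0 = 1.3, amp = 0.9,
                                       alpha = 2.0, e_inf = 3.7, offset = 0,
                                       masses = c(2.0, 2.0),
                                       labels = c("D", "D")) {
  .check_positive(k = k, alpha = alpha)
  stopifnot(length(masses) == 2L, all(masses > 0))
  k_au <- to_au(k, "energy") / to_au(1, "length")^2
  r0_au <- to_au(r0, "length")
  amp_au <- to_au(amp, "energy")
  alpha_au <- alpha / to_au(1, "length")
  e_inf_au <- to_au(e_inf, "energy")
  offset_au <- to_au(offset, "energy")
  anion <- .valence_surface(
    "toy_diatomic_anion", 2L,
    list(function(q) {
      res <- .term_bond_harmonic(q, 1L, 2L, r0_au, k_au)
      res$energy <- res$energy + offset_au
      res
    }),
    params = list(k = k, r0 = r0, offset = offset)
  )
  neutral <- .valence_surface(
    "toy_diatomic_neutral", 2L,
    list(function(q) .term_bond_repulsive(q, 1L, 2L, r0_au, amp_au,
                                          alpha_au, e_inf_au)),
    params = list(amp = amp, alpha = alpha, e_inf = e_inf, r0 = r0)
  )
  template <- rbind(c(-r0 / 2, 0, 0), c(r0 / 2, 0, 0))
  surface_pair(
    anion, neutral, masses = masses, labels = labels, template = template,
    meta = list(system = "toy_diatomic",
                fragments = list(a = 1L, b = 2L),
                params = list(k = k, r0 = r0, amp = amp, alpha = alpha,
                              e_inf = e_inf, offset = offset))
  )
}

#' Four-atom torsional toy photodetachment system
#'
#' An H-O-C-O chain whose anionic state binds all valence coordinates and
#' whose neutral state is repulsive along the central O-C bond, so vertical
#' detachment dissociates the molecule into an OH-like and a CO-like
#' fragment while the H-O-C-O torsion carries the cis/trans memory. The
#' torsional potential \eqn{(V_2/2)(1 - \cos 2\phi)} has wells at
#' \eqn{\phi = 0} (cis) and \eqn{\phi = 180^\circ} (trans) separated by a
#' barrier \eqn{V_2 \gg k_B T}, so thermal sampling started in one well
#' stays there and the dissociating fragments retain the starting isomer —
#' the mechanism behind isomer-selective product formation.
#'
#' @param start `"trans"` or `"cis"`: which torsional well the template
#'   geometry occupies.
#' @param v2 Torsional barrier, eV.
#' @param amp,alpha,e_inf Neutral repulsion amplitude (eV), range
#'   (1/angstrom) and asymptote (eV) along the central bond.
#' @param k_oh,k_oc,k_co Bond force constants, eV/angstrom^2 (H-O, central
#'   O-C, terminal C-O).
#' @param r_oh,r_oc,r_co Equilibrium bond lengths, angstrom.
#' @param theta_hoc,theta_oco Equilibrium angles, degrees.
#' @param k_ang Angle force constant, eV/rad^2.
#' @return A [surface_pair()]; `meta` declares the fragments
#'   (`{H, O}` vs `{C, O}`) and the 1-2-3-4 dihedral.
#' @export
toy_torsional_system <- function(start = c("trans", "cis"), v2 = 1.0,
                                 amp = 0.9, alpha = 2.0, e_inf = 3.7,
                                 k_oh = 35, k_oc = 20, k_co = 45,
                                 r_oh = 0.97, r_oc = 1.40, r_co = 1.20,
                                 theta_hoc = 105, theta_oco = 127,
                                 k_ang = 3.0) {
  start <- match.arg(start)
  .check_positive(v2 = v2, alpha = alpha, k_oh = k_oh, k_oc = k_oc,
                  k_co = k_co, k_ang = k_ang)
  fl <- to_au(1, "length")
  kk <- function(x) to_au(x, "energy") / fl^2
  bonded <- list(
    function(q) .term_bond_harmonic(q, 1L, 2L, to_au(r_oh, "length"), kk(k_oh)),
    function(q) .term_bond_harmonic(q, 3L, 4L, to_au(r_co, "length"), kk(k_co)),
    function(q) .term_angle_harmonic(q, 1L, 2L, 3L, theta_hoc * pi / 180,
                                     to_au(k_ang, "energy")),
    function(q) .term_angle_harmonic(q, 2L, 3L, 4L, theta_oco * pi / 180,
                                     to_au(k_ang, "energy")),
    function(q) .term_torsion_double_well(q, 1L, 2L, 3L, 4L,
                                          to_au(v2, "energy"))
  )
  anion_terms <- c(bonded, list(
    function(q) .term_bond_harmonic(q, 2L, 3L, to_au(r_oc, "length"), kk(k_oc))
  ))
  neutral_terms <- c(bonded, list(
    function(q) .term_bond_repulsive(q, 2L, 3L, to_au(r_oc, "length"),
                                     to_au(amp, "energy"), alpha / fl,
                                     to_au(e_inf, "energy"))
  ))
  params <- list(v2 = v2, amp = amp, alpha = alpha, e_inf = e_inf)
  anion <- .valence_surface("toy_torsional_anion", 4L, anion_terms, params)
  neutral <- .valence_surface("toy_torsional_neutral", 4L, neutral_terms, params)

  # planar template: O2 at origin, C along +x; H in the xy-plane; the
  # terminal O anti (trans) or eclipsed (cis) with respect to H
  th1 <- theta_hoc * pi / 180
  th2 <- pi - theta_oco * pi / 180
  h <- c(r_oh * cos(th1), r_oh * sin(th1), 0)
  o2 <- c(0, 0, 0)
  cc <- c(r_oc, 0, 0)
  y_sign <- if (start == "trans") -1 else 1
  o4 <- cc + c(r_co * cos(th2), y_sign * r_co * sin(th2), 0)
  template <- rbind(h, o2, cc, o4)
  rownames(template) <- NULL
  surface_pair(
    anion, neutral,
    masses = c(1.008, 15.999, 12.011, 15.999),
    labels = c("H", "O", "C", "O"),
    template = template,
    meta = list(system = "toy_torsional", start = start,
                fragments = list(a = c(1L, 2L), b = c(3L, 4L)),
                dihedral = c(1L, 2L, 3L, 4L), params = params)
  )
}
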