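# Potential-surface contract. A surface is a set of closures working in
# internal atomic units on ndof x m coordinate matrices (one column per
# geometry), so bead-parallel evaluation is a single call. Constructors take
# interface units (eV, angstrom) unless units = "au".

#' Potential-energy surface contract
#'
#' A `potential_surface` supplies the energy and gradient (and optionally an
#' analytic Hessian) at any finite geometry of its declared dimensionality.
#' It stands in for on-the-fly electronic structure: the simulator only ever
#' talks to this contract, so analytic models and user-supplied callables are
#' interchangeable.
#'
#' All closures work in internal atomic units. `energy` and `gradient` must
#' accept an `ndof x m` matrix (one geometry per column) and return a
#' length-`m` vector / `ndof x m` matrix; `hessian`, if given, takes a single
#' geometry vector and returns an `ndof x ndof` matrix.
#'
#' @param name Identifier.
#' @param ndof Number of Cartesian degrees of freedom (3 x atoms for
#'   molecular surfaces).
#' @param energy,gradient,hessian Closures as described above; `hessian` may
#'   be `NULL` (a symmetrized central finite difference of the gradient is
#'   used instead, see [surface_hessian()]).
#' @param params Named list of the surface's parameters, kept for
#'   provenance/metadata.
#' @return An object of class `potential_surface`.
#' @export
potential_surface <- function(name, ndof, energy, gradient, hessian = NULL,
                              params = list()) {
  stopifnot(is.function(energy), is.function(gradient),
            is.null(hessian) || is.function(hessian), ndof >= 1)
  structure(
    list(name = name, ndof = as.integer(ndof), energy = energy,
         gradient = gradient, hessian = hessian,
         has_analytic_hessian = !is.null(hessian), params = params),
    class = "potential_surface"
  )
}

#' @export
print.potential_surface <- function(x, ...) {
  cat(sprintf("<potential_surface> %s (ndof = %d, analytic hessian: %s)\n",
              x$name, x$ndof, x$has_analytic_hessian))
  invisible(x)
}

.as_coord_matrix <- function(pes, q) {
  if (is.null(dim(q))) q <- matrix(q, ncol = 1L)
  if (nrow(q) != pes$ndof) {
    rlang::abort(sprintf("surface '%s' expects %d coordinates, got %d",
                         pes$name, pes$ndof, nrow(q)),
                 class = "rpdyn_surface_error")
  }
  if (!all(is.finite(q))) {
    bad <- which(!is.finite(q), arr.ind = TRUE)[1, ]
    rlang::abort(sprintf(
      "non-finite geometry passed to surface '%s' (coordinate %d of geometry %d)",
      pes$name, bad[[1]], bad[[2]]), class = "rpdyn_surface_error")
  }
  q
}

#' Evaluate a potential surface
#'
#' @param pes A [potential_surface()].
#' @param q Geometry: a length-`ndof` vector or an `ndof x m` matrix
#'   (internal atomic units).
#' @return `surface_energy`: energy (hartree), one value per geometry;
#'   `surface_gradient`: gradient matrix `ndof x m` (hartree/bohr).
#' @export
surface_energy <- function(pes, q) {
  pes$energy(.as_coord_matrix(pes, q))
}

#' @rdname surface_energy
#' @export
surface_gradient <- function(pes, q) {
  pes$gradient(.as_coord_matrix(pes, q))
}

#' Hessian of a potential surface
#'
#' Uses the analytic Hessian when the surface provides one; otherwise a
#' symmetrized central finite difference of the gradient,
#' \eqn{(H + H^T)/2}, with displacement `step`.
#'
#' @inheritParams surface_energy
#' @param q A single geometry (length-`ndof` vector).
#' @param step Finite-difference displacement in bohr (default corresponds
#'   to 1e-3 angstrom).
#' @return An `ndof x ndof` matrix (hartree/bohr^2).
#' @export
surface_hessian <- function(pes, q, step = to_au(1e-3, "length")) {
  q <- drop(.as_coord_matrix(pes, q))
  if (pes$has_analytic_hessian) return(pes$hessian(q))
  stopifnot(step > 0)
  n <- pes$ndof
  disp <- matrix(rep(q, 2L * n), nrow = n)
  idx <- cbind(rep(seq_len(n), each = 2L), seq_len(2L * n))
  disp[idx] <- disp[idx] + rep(c(step, -step), n)
  g <- pes$gradient(disp)
  h <- (g[, seq(1L, 2L * n, by = 2L), drop = FALSE] -
          g[, seq(2L, 2L * n, by = 2L), drop = FALSE]) / (2 * step)
  (h + t(h)) / 2
}

.check_positive <- function(...) {
  vals <- list(...)
  for (nm in names(vals)) {
    if (any(vals[[nm]] <= 0)) {
      rlang::abort(sprintf("parameter '%s' must be positive", nm),
                   class = "rpdyn_parameter_error")
    }
  }
  invisible(NULL)
}

#' Harmonic (quadratic diagonal) surface
#'
#' \eqn{V(q) = \sum_d \tfrac12 k_d (q_d - q_{0,d})^2}.
#'
#' @param k Force constant(s), eV/angstrom^2 (recycled over dimensions).
#' @param x0 Minimum position, angstrom; its length sets `ndof`.
#' @param units `"real"` (eV, angstrom) or `"au"`.
#' @return A [potential_surface()] with analytic Hessian.
#' @export
harmonic_surface <- function(k, x0 = 0, units = c("real", "au")) {
  units <- match.arg(units)
  ndof <- length(x0)
  k <- rep_len(k, ndof)
  .check_positive(k = k)
  if (units == "real") {
    k <- to_au(k, "energy") / to_au(1, "length")^2
    x0 <- to_au(x0, "length")
  }
  potential_surface(
    name = "harmonic", ndof = ndof,
    energy = function(q) colSums(k * (q - x0)^2) / 2,
    gradient = function(q) k * (q - x0),
    hessian = function(q) diag(k, ndof),
    params = list(k = k, x0 = x0)
  )
}

#' General quadratic surface
#'
#' \eqn{V(q) = e_0 + g_0^T (q - q_0) + \tfrac12 (q - q_0)^T H (q - q_0)}.
#' Useful as the "any quadratic surface" fixture: the centroid Taylor force
#' approximation is exact on it.
#'
#' @param hessian Symmetric `ndof x ndof` matrix, eV/angstrom^2.
#' @param gradient0 Gradient at `q0`, eV/angstrom (default zero).
#' @param q0 Expansion point, angstrom (default origin).
#' @param e0 Energy at `q0`, eV.
#' @inheritParams harmonic_surface
#' @return A [potential_surface()] with analytic Hessian.
#' @export
quadratic_surface <- function(hessian, gradient0 = NULL, q0 = NULL, e0 = 0,
                              units = c("real", "au")) {
  units <- match.arg(units)
  hessian <- as.matrix(hessian)
  ndof <- nrow(hessian)
  stopifnot(ncol(hessian) == ndof, isTRUE(all.equal(hessian, t(hessian))))
  if (is.null(gradient0)) gradient0 <- numeric(ndof)
  if (is.null(q0)) q0 <- numeric(ndof)
  if (units == "real") {
    fl <- to_au(1, "length")
    hessian <- to_au(hessian, "energy") / fl^2
    gradient0 <- to_au(gradient0, "energy") / fl
    q0 <- to_au(q0, "length")
    e0 <- to_au(e0, "energy")
  }
  potential_surface(
    name = "quadratic", ndof = ndof,
    energy = function(q) {
      dq <- q - q0
      e0 + colSums(gradient0 * dq) + colSums(dq * (hessian %*% dq)) / 2
    },
    gradient = function(q) gradient0 + hessian %*% (q - q0),
    hessian = function(q) hessian,
    params = list(hessian = hessian, gradient0 = gradient0, q0 = q0, e0 = e0)
  )
}

#' One-dimensional Morse surface
#'
#' \eqn{V(r) = D_e (1 - e^{-a (r - r_e)})^2}, `ndof = 1`.
#'
#' @param de Well depth, eV.
#' @param a Range parameter, 1/angstrom.
#' @param re Equilibrium distance, angstrom.
#' @inheritParams harmonic_surface
#' @export
morse_surface <- function(de, a, re, units = c("real", "au")) {
  units <- match.arg(units)
  .check_positive(de = de, a = a)
  if (units == "real") {
    de <- to_au(de, "energy")
    a <- a / to_au(1, "length")
    re <- to_au(re, "length")
  }
  potential_surface(
    name = "morse", ndof = 1L,
    energy = function(q) {
      ex <- exp(-a * (q[1, ] - re)); de * (1 - ex)^2
    },
    gradient = function(q) {
      ex <- exp(-a * (q[1, ] - re))
      matrix(2 * de * a * ex * (1 - ex), nrow = 1L)
    },
    params = list(de = de, a = a, re = re)
  )
}

#' Quartic double-well surface (one atom, 3D)
#'
#' \eqn{V = V_0 (x^2 - a^2)^2 / a^4 + \tfrac12 k_t (y^2 + z^2)}: symmetric
#' wells at \eqn{x = \pm a} separated by a barrier \eqn{V_0}, with a
#' harmonic transverse restraint. Emulates two isomers separated by a high
#' barrier: with \eqn{V_0 \gg k_B T} a thermal simulation started in one
#' well stays there.
#'
#' @param v0 Barrier height, eV.
#' @param a Well position, angstrom.
#' @param k_t Transverse force constant, eV/angstrom^2; defaults to the
#'   curvature at the well bottom, \eqn{8 V_0 / a^2}.
#' @inheritParams harmonic_surface
#' @export
double_well_surface <- function(v0, a, k_t = NULL, units = c("real", "au")) {
  units <- match.arg(units)
  .check_positive(v0 = v0, a = a)
  if (is.null(k_t)) k_t <- 8 * v0 / a^2
  .check_positive(k_t = k_t)
  if (units == "real") {
    fl <- to_au(1, "length")
    v0 <- to_au(v0, "energy"); a <- to_au(a, "length")
    k_t <- to_au(k_t, "energy") / fl^2
  }
  potential_surface(
    name = "double_well", ndof = 3L,
    energy = function(q) {
      v0 * (q[1, ]^2 - a^2)^2 / a^4 + k_t * (q[2, ]^2 + q[3, ]^2) / 2
    },
    gradient = function(q) {
      rbind(4 * v0 * q[1, ] * (q[1, ]^2 - a^2) / a^4,
            k_t * q[2, ], k_t * q[3, ])
    },
    params = list(v0 = v0, a = a, k_t = k_t)
  )
}

#' Cubic test surface
#'
#' \eqn{V = c x^3} on the first coordinate of one atom (others flat). The
#' standard fixture for the Taylor force-approximation error: at a centroid
#' at the origin the second-order expansion predicts zero gradient while the
#' true per-bead gradient is \eqn{3 c \delta^2}.
#'
#' @param c3 Cubic coefficient, eV/angstrom^3.
#' @inheritParams harmonic_surface
#' @export
cubic_surface <- function(c3 = 1, units = c("real", "au")) {
  units <- match.arg(units)
  if (units == "real") c3 <- to_au(c3, "energy") / to_au(1, "length")^3
  potential_surface(
    name = "cubic", ndof = 3L,
    energy = function(q) c3 * q[1, ]^3,
    gradient = function(q) rbind(3 * c3 * q[1, ]^2, 0 * q[2, ], 0 * q[3, ]),
    hessian = function(q) diag(c(6 * c3 * q[1], 0, 0)),
    params = list(c3 = c3)
  )
}

#' Linear surface
#'
#' \eqn{V(q) = a^T q + b}. With a Gaussian coordinate density, the induced
#' energy-gap distribution is Gaussian — the exactly solvable case of the
#' reflection principle.
#'
#' @param slope Gradient vector `a`, eV/angstrom; its length sets `ndof`.
#' @param intercept Offset `b`, eV.
#' @inheritParams harmonic_surface
#' @export
linear_surface <- function(slope, intercept = 0, units = c("real", "au")) {
  units <- match.arg(units)
  ndof <- length(slope)
  if (units == "real") {
    slope <- to_au(slope, "energy") / to_au(1, "length")
    intercept <- to_au(intercept, "energy")
  }
  potential_surface(
    name = "linear", ndof = ndof,
    energy = function(q) colSums(slope * q) + intercept,
    gradient = function(q) matrix(slope, ndof, ncol(q)),
    hessian = function(q) matrix(0, ndof, ndof),
    params = list(slope = slope, intercept = intercept)
  )
}

#' Shift a surface by a constant
#'
#' @param pes A [potential_surface()].
#' @param offset Energy offset, eV (or hartree with `units = "au"`).
#' @inheritParams harmonic_surface
#' @export
shift_surface <- function(pes, offset, units = c("real", "au")) {
  units <- match.arg(units)
  if (units == "real") offset <- to_au(offset, "energy")
  potential_surface(
    name = paste0(pes$name, "+const"), ndof = pes$ndof,
    energy = function(q) pes$energy(q) + offset,
    gradient = pes$gradient, hessian = pes$hessian,
    params = c(pes$params, list(offset = offset))
  )
}

#' Anion/neutral surface pair
#'
#' The pair of surfaces driving the photodetachment workflow: the bound
#' anionic state sampled thermally and the neutral state reached by vertical
#' electron detachment. Both must share geometry layout.
#'
#' @param anion,neutral [potential_surface()] objects with equal `ndof`.
#' @param masses Atomic masses (amu) of the shared geometry layout; optional
#'   for purely mathematical pairs.
#' @param labels Per-atom element labels.
#' @param template Reference geometry (`n_atoms x 3`, angstrom), typically
#'   the anion minimum; used to seed sampling.
#' @param meta Named list of extra metadata (fragment definitions, dihedral
#'   indices, ...).
#' @return An object of class `surface_pair`.
#' @export
surface_pair <- function(anion, neutral, masses = NULL, labels = NULL,
                         template = NULL, meta = list()) {
  stopifnot(inherits(anion, "potential_surface"),
            inherits(neutral, "potential_surface"))
  if (anion$ndof != neutral$ndof) {
    rlang::abort("anion and neutral surfaces must share dimensionality",
                 class = "rpdyn_surface_error")
  }
  structure(
    list(anion = anion, neutral = neutral, ndof = anion$ndof,
         masses = masses, labels = labels, template = template, meta = meta),
    class = "surface_pair"
  )
}

#' @export
print.surface_pair <- function(x, ...) {
  cat(sprintf("<surface_pair> anion: %s | neutral: %s (ndof = %d)\n",
              x$anion$name, x$neutral$name, x$ndof))
  invisible(x)
}
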