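# Centroid second-order Taylor expansion of the bead forces: the gradient at
# every bead is approximated by the gradient at the bead centroid plus the
# centroid Hessian times the bead displacement. One gradient and one Hessian
# per step replace N gradient evaluations — the approximation that makes
# on-the-fly quantum thermal sampling affordable, valid while the bead
# spread around the centroid is small (roughly T > 200 K for molecules).

#' Force-evaluation mode
#'
#' @param mode `"exact_beads"` (true gradient at every bead) or
#'   `"centroid_taylor"` (second-order Taylor expansion at the centroid).
#' @param hessian_step Finite-difference displacement used when the surface
#'   has no analytic Hessian, angstrom.
#' @param hessian_stride Steps between Hessian refreshes during dynamics;
#'   1 recomputes at the current centroid every step.
#' @return An object of class `force_mode`.
#' @export
force_mode <- function(mode = c("exact_beads", "centroid_taylor"),
                       hessian_step = 1e-3, hessian_stride = 1L) {
  mode <- match.arg(mode)
  stopifnot(hessian_step > 0, hessian_stride >= 1)
  structure(
    list(mode = mode, hessian_step = hessian_step,
         hessian_stride = as.integer(hessian_stride)),
    class = "force_mode"
  )
}

.as_force_mode <- function(mode) {
  if (inherits(mode, "force_mode")) return(mode)
  force_mode(mode)
}

#' Per-bead potential gradients, exact or centroid-Taylor
#'
#' With `mode = "exact_beads"` returns the true gradient
#' \eqn{\partial V/\partial Q} at every bead. With
#' `mode = "centroid_taylor"` returns
#' \deqn{\left(\frac{\partial V}{\partial Q}\right)_{Q_c}
#'   + \left(\frac{\partial^2 V}{\partial Q^2}\right)_{Q_c} (Q_s - Q_c),}
#' which is exact for quadratic surfaces and has an error growing as the
#' square of the bead spread otherwise.
#'
#' @param pes A [potential_surface()] (for a [surface_pair()] pass the
#'   member surface explicitly).
#' @param cfg A [bead_configuration()].
#' @param mode A [force_mode()] or mode string.
#' @return An `ndof x n_beads` matrix of gradients, hartree/bohr.
#' @export
taylor_bead_forces <- function(pes, cfg, mode = "centroid_taylor") {
  mode <- .as_force_mode(mode)
  .bead_gradients(pes, cfg$positions, mode)
}

# pos: ndof x n_beads (internal units). cache: optional environment with
# fields `hessian`, `age` used to honor hessian_stride across steps.
.bead_gradients <- function(pes, pos, mode, cache = NULL) {
  if (mode$mode == "exact_beads") {
    return(surface_gradient(pes, pos))
  }
  qc <- rowMeans(pos)
  g0 <- drop(surface_gradient(pes, qc))
  h <- NULL
  if (!is.null(cache) && !is.null(cache$hessian) && cache$age < mode$hessian_stride) {
    h <- cache$hessian
    cache$age <- cache$age + 1L
  }
  if (is.null(h)) {
    h <- tryCatch(
      surface_hessian(pes, qc, step = to_au(mode$hessian_step, "length")),
      error = function(e) {
        rlang::abort(
          paste0("Hessian evaluation failed at centroid [",
                 paste(signif(from_au(qc, "length"), 6), collapse = ", "),
                 "] angstrom: ", conditionMessage(e)),
          class = "rpdyn_surface_error", parent = e)
      })
    if (!is.null(cache)) {
      cache$hessian <- h
      cache$age <- 1L
    }
  }
  g0 + h %*% (pos - qc)
}
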