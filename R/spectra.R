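# Semiclassical photoelectron spectrum: the thermal nuclear density mapped
# through the vertical energy gap,
#   I(E_b) ~ integral delta(E_b - V_n(Q) + V_a(Q)) rho_a(Q) dQ,
# realized as a (optionally kernel-smoothed) histogram over gap samples.
# Plus the 2D photoelectron-photofragment coincidence histogram N(E_k, E_b).

#' Vertical electron binding energy
#'
#' \eqn{E_b(Q) = V_n(Q) - V_a(Q)}: the energy to remove the electron at
#' frozen nuclear geometry, measured from the anion surface.
#'
#' @param pair A [surface_pair()].
#' @param geometry An `n_atoms x 3` matrix in angstrom (default) or a
#'   length-`ndof` vector / `ndof x m` matrix in bohr with `units = "au"`.
#' @param units Geometry units.
#' @return Binding energy in eV, one value per geometry.
#' @export
binding_energy <- function(pair, geometry, units = c("angstrom", "au")) {
  units <- match.arg(units)
  q <- if (units == "angstrom") {
    stopifnot(is.matrix(geometry), ncol(geometry) == 3L)
    matrix(to_au(.flatten_geometry(geometry), "length"), ncol = 1L)
  } else geometry
  from_au(surface_energy(pair$neutral, q) - surface_energy(pair$anion, q),
          "energy")
}

.ensemble_gap_samples <- function(ensemble, pair,
                                  convention = c("per_bead", "per_centroid")) {
  convention <- match.arg(convention)
  q <- if (convention == "per_bead") .ensemble_bead_matrix(ensemble)
       else .ensemble_centroid_matrix(ensemble)
  from_au(surface_energy(pair$neutral, q) - surface_energy(pair$anion, q),
          "energy")
}

#' Semiclassical photoelectron spectrum
#'
#' Histograms the vertical gap \eqn{V_n - V_a} over a thermal ensemble.
#' Under the `"per_bead"` convention (default) every bead contributes one
#' sample — bead positions are samples of the quantum nuclear density, so
#' this is the direct realization of the semiclassical delta-function
#' integral. `"per_centroid"` evaluates the gap at bead centroids instead;
#' the two coincide for one bead.
#'
#' @param ensemble An `rp_ensemble`.
#' @param pair A [surface_pair()].
#' @param bin_width Histogram bin width, eV.
#' @param bins Optional explicit bin edges (eV), overriding `bin_width`.
#' @param convention `"per_bead"` or `"per_centroid"`.
#' @param kernel_sigma Optional Gaussian smoothing width, eV.
#' @return An object of class `rp_spectrum`: a tibble-backed histogram with
#'   unit integral, plus the raw sample mean/sd (`mean_ev`, `sd_ev`) and
#'   sample count.
#' @export
photoelectron_spectrum <- function(ensemble, pair, bin_width = 0.02,
                                   bins = NULL,
                                   convention = c("per_bead", "per_centroid"),
                                   kernel_sigma = NULL) {
  convention <- match.arg(convention)
  stopifnot(inherits(ensemble, "rp_ensemble"))
  if (length(ensemble$samples) == 0L) {
    rlang::abort("empty ensemble", class = "rpdyn_state_error")
  }
  eb <- .ensemble_gap_samples(ensemble, pair, convention)
  if (is.null(bins)) {
    lo <- floor(min(eb) / bin_width) * bin_width - bin_width
    hi <- ceiling(max(eb) / bin_width) * bin_width + bin_width
    bins <- seq(lo, hi, by = bin_width)
  }
  stopifnot(length(bins) >= 2, all(diff(bins) > 0))
  h <- graphics::hist(eb, breaks = bins, plot = FALSE)
  density <- h$density
  if (!is.null(kernel_sigma)) {
    stopifnot(kernel_sigma > 0)
    mids <- h$mids
    w <- outer(mids, mids, function(a, b) stats::dnorm(a - b, sd = kernel_sigma))
    widths <- diff(bins)
    density <- as.vector(w %*% (density * widths))
    density <- density / sum(density * widths)
  }
  structure(
    list(
      table = tibble::tibble(e_b = h$mids, density = density),
      edges = bins, convention = convention,
      sample_count = length(eb), mean_ev = mean(eb),
      sd_ev = stats::sd(eb),
      provenance = ensemble$provenance
    ),
    class = "rp_spectrum"
  )
}

#' @export
print.rp_spectrum <- function(x, ...) {
  cat(sprintf(
    "<rp_spectrum> %d samples (%s), mean E_b = %.3f eV, sd = %.3f eV\n",
    x$sample_count, x$convention, x$mean_ev, x$sd_ev))
  invisible(x)
}

#' Summary moments of a spectrum histogram
#'
#' Mean and standard deviation implied by the binned density (useful when
#' only the histogram is available; the raw-sample moments are stored on
#' the object as `mean_ev`/`sd_ev`).
#'
#' @param spectrum An `rp_spectrum`.
#' @return Named vector with `mean` and `sd` (eV).
#' @export
spectrum_moments <- function(spectrum) {
  w <- spectrum$table$density * diff(spectrum$edges)
  w <- w / sum(w)
  m <- sum(w * spectrum$table$e_b)
  c(mean = m, sd = sqrt(sum(w * (spectrum$table$e_b - m)^2)))
}

#' Photoelectron-photofragment coincidence spectrum
#'
#' The joint histogram \eqn{N(E_k, E_b)} of fragment kinetic-energy release
#' and electron binding energy over dissociated trajectories. Undissociated
#' or failed records are excluded and counted in `n_excluded`; the marginal
#' histograms of the included records equal the corresponding 1D
#' histograms by construction.
#'
#' @param records A tibble of product records (see [analyze_products()])
#'   with columns `e_k`, `e_b` and `channel`.
#' @param ek_bins,eb_bins Bin edges, eV; defaults span the data with
#'   0.05 eV bins.
#' @return An object of class `rp_coincidence` with a counts matrix
#'   (`E_k` rows, `E_b` columns), a long-format tibble, and `n_excluded`.
#' @export
coincidence_spectrum <- function(records, ek_bins = NULL, eb_bins = NULL) {
  stopifnot(is.data.frame(records),
            all(c("e_k", "e_b", "channel") %in% names(records)))
  keep <- records$channel %in% c("cis", "trans") &
    is.finite(records$e_k) & is.finite(records$e_b)
  n_excluded <- sum(!keep)
  rec <- records[keep, , drop = FALSE]
  if (nrow(rec) == 0L) {
    rlang::abort("no dissociated records to histogram",
                 class = "rpdyn_state_error")
  }
  stopifnot(all(rec$e_k >= 0))
  default_bins <- function(x, width = 0.05) {
    seq(floor(min(x) / width) * width - width,
        ceiling(max(x) / width) * width + width, by = width)
  }
  if (is.null(ek_bins)) ek_bins <- default_bins(rec$e_k)
  if (is.null(eb_bins)) eb_bins <- default_bins(rec$e_b)
  ik <- cut(rec$e_k, ek_bins, include.lowest = TRUE, labels = FALSE)
  ib <- cut(rec$e_b, eb_bins, include.lowest = TRUE, labels = FALSE)
  counts <- matrix(0L, length(ek_bins) - 1L, length(eb_bins) - 1L)
  for (r in seq_along(ik)) {
    counts[ik[r], ib[r]] <- counts[ik[r], ib[r]] + 1L
  }
  mid <- function(edges) (edges[-1] + edges[-length(edges)]) / 2
  # counts is column-major (E_k varies fastest), so put e_k innermost
  long <- tidyr::expand_grid(e_b = mid(eb_bins), e_k = mid(ek_bins))
  long$count <- as.vector(counts)
  long <- long[, c("e_k", "e_b", "count")]
  structure(
    list(counts = counts, ek_edges = ek_bins, eb_edges = eb_bins,
         table = tibble::as_tibble(long), n_included = nrow(rec),
         n_excluded = n_excluded),
    class = "rp_coincidence"
  )
}

#' @export
print.rp_coincidence <- function(x, ...) {
  cat(sprintf("<rp_coincidence> %d event(s) on a %d x %d (E_k x E_b) grid, %d excluded\n",
              x$n_included, nrow(x$counts), ncol(x$counts), x$n_excluded))
  invisible(x)
}

#' Marginal histograms of a coincidence spectrum
#'
#' @param coincidence An `rp_coincidence`.
#' @return A list of two tibbles, `e_k` and `e_b`, with bin mids and counts.
#' @export
coincidence_marginals <- function(coincidence) {
  mid <- function(edges) (edges[-1] + edges[-length(edges)]) / 2
  list(
    e_k = tibble::tibble(e_k = mid(coincidence$ek_edges),
                         count = rowSums(coincidence$counts)),
    e_b = tibble::tibble(e_b = mid(coincidence$eb_edges),
                         count = colSums(coincidence$counts))
  )
}
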