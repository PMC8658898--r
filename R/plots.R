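# ggplot2 front-ends for the result types.

#' Plot a photoelectron spectrum
#'
#' @param object An `rp_spectrum`.
#' @param ... Unused.
#' @return A ggplot object: normalized intensity against electron binding
#'   energy.
#' @export
autoplot.rp_spectrum <- function(object, ...) {
  ggplot2::ggplot(object$table, ggplot2::aes(x = .data$e_b, y = .data$density)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "electron binding energy E_b (eV)",
                  y = "I(E_b) (1/eV)",
                  title = sprintf("Photoelectron spectrum (%s, n = %d)",
                                  object$convention, object$sample_count)) +
    ggplot2::theme_minimal()
}

#' Plot a coincidence spectrum
#'
#' @param object An `rp_coincidence`.
#' @param ... Unused.
#' @return A ggplot tile map of `N(E_k, E_b)`.
#' @export
autoplot.rp_coincidence <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = .data$e_b, y = .data$e_k,
                               fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "electron binding energy E_b (eV)",
                  y = "kinetic energy release E_k (eV)",
                  fill = "N") +
    ggplot2::theme_minimal()
}

#' Dihedral distribution of product records
#'
#' Histogram of final dihedrals in the (-90, 270] reporting range, colored
#' by assigned channel, with the cis/trans decision boundary marked.
#'
#' @param records A product tibble from [analyze_products()].
#' @param binwidth Bin width, degrees.
#' @return A ggplot object.
#' @export
plot_dihedral_distribution <- function(records, binwidth = 5) {
  rec <- records[is.finite(records$dihedral), , drop = FALSE]
  ggplot2::ggplot(rec, ggplot2::aes(x = .data$dihedral,
                                    fill = .data$channel)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = -90) +
    ggplot2::geom_vline(xintercept = 90, linetype = "dashed") +
    ggplot2::scale_x_continuous(limits = c(-90, 270)) +
    ggplot2::labs(x = "final H-O-C-O dihedral (degrees)", y = "trajectories") +
    ggplot2::theme_minimal()
}

#' Relative-velocity time series of a trajectory set
#'
#' The diagnostic view of dissociation dynamics: fragment relative speed
#' against time for every trajectory; the plateau marks completed
#' dissociation.
#'
#' @param trajectories An `rp_trajectory_set`.
#' @param fragments A [fragment_definition()] or list with `a`, `b`.
#' @return A ggplot object.
#' @export
plot_relative_velocity <- function(trajectories, fragments) {
  df <- purrr::imap_dfr(trajectories$trajectories, function(tr, i) {
    s <- .trajectory_fragment_series(tr, fragments)
    tibble::tibble(trajectory = i, time_fs = tr$time_fs, speed = s$speed)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_fs, y = .data$speed,
                                   group = .data$trajectory)) +
    ggplot2::geom_line(alpha = 0.3) +
    ggplot2::labs(x = "time (fs)", y = "relative speed (angstrom/fs)") +
    ggplot2::theme_minimal()
}
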