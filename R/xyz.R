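# Multi-frame XYZ reader/writer: atom-count line, free-form comment line,
# then one "element x y z" line per atom; frames concatenated.

#' Read a (multi-frame) XYZ file
#'
#' @param path File path.
#' @return A list of frames, each a list with `labels` (character),
#'   `coords` (`n_atoms x 3` matrix, angstrom) and `comment`. An empty
#'   file yields an empty list.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) {
      i <- i + 1L
      next
    }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L) {
      rlang::abort(sprintf("line %d: expected an atom count, got '%s'",
                           i, lines[i]), class = "rpdyn_parse_error")
    }
    if (i + 1L + n > length(lines)) {
      rlang::abort(sprintf(
        "line %d: frame declares %d atoms but the file ends after line %d",
        i, n, length(lines)), class = "rpdyn_parse_error")
    }
    comment <- lines[i + 1L]
    labels <- character(n)
    coords <- matrix(NA_real_, n, 3L)
    for (a in seq_len(n)) {
      ln <- i + 1L + a
      parts <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
      if (length(parts) < 4L) {
        rlang::abort(sprintf("line %d: expected 'element x y z', got '%s'",
                             ln, lines[ln]), class = "rpdyn_parse_error")
      }
      xyz <- suppressWarnings(as.numeric(parts[2:4]))
      if (any(is.na(xyz))) {
        rlang::abort(sprintf("line %d: non-numeric coordinate in '%s'",
                             ln, lines[ln]), class = "rpdyn_parse_error")
      }
      labels[a] <- parts[1]
      coords[a, ] <- xyz
    }
    frames[[length(frames) + 1L]] <-
      list(labels = labels, coords = coords, comment = comment)
    i <- i + 2L + n
  }
  frames
}

#' Write frames to an XYZ file
#'
#' @param frames A single frame (list with `labels`, `coords`, optional
#'   `comment`) or a list of such frames. Coordinates in angstrom.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(frames, path) {
  if (!is.null(frames$coords)) frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    stopifnot(is.matrix(fr$coords), ncol(fr$coords) == 3L,
              length(fr$labels) == nrow(fr$coords))
    writeLines(as.character(nrow(fr$coords)), con)
    writeLines(fr$comment %||% "", con)
    writeLines(sprintf("%-4s %18.10f %18.10f %18.10f", fr$labels,
                       fr$coords[, 1], fr$coords[, 2], fr$coords[, 3]), con)
  }
  invisible(path)
}

#' Export centroid frames of a trajectory as multi-frame XYZ
#'
#' @param traj An `rp_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_xyz <- function(traj, path) {
  frames <- lapply(seq_along(traj$time_fs), function(i) {
    list(labels = traj$labels,
         coords = .unflatten_geometry(traj$centroid_positions[i, ]),
         comment = sprintf("t = %.4f fs  status = %s", traj$time_fs[i],
                           traj$status))
  })
  write_xyz(frames, path)
}
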