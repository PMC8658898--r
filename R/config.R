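# Declarative run configuration: a versioned YAML document with nested
# blocks (system / surfaces / sampler / dynamics / analysis), validated
# before any computation; unknown keys are rejected with their location.

.config_schema <- list(
  schema = NULL, seed = NULL, output_dir = NULL,
  system = c("geometry_file", "start"),
  surfaces = c("pair", "params"),
  sampler = c("temperature", "n_beads", "dt", "n_steps", "burn_in",
              "sample_stride", "force_mode", "hessian_stride", "jitter"),
  dynamics = c("dt", "max_steps", "n_trajectories", "stop_rule", "r_diss",
               "record_stride", "force_mode"),
  analysis = c("fragments_a", "fragments_b", "dihedral", "eb_bin_width",
               "ek_bin_width", "plateau_tol", "window", "cutoff")
)

.builtin_pairs <- function() {
  list(
    toy_diatomic = function(params, start = NULL) {
      do.call(toy_photodetachment_system, params)
    },
    toy_torsional = function(params, start = NULL) {
      do.call(toy_torsional_system,
              c(list(start = start %||% "trans"), params))
    }
  )
}

.pair_registry <- new.env(parent = emptyenv())

#' Register a surface pair constructor for configuration files
#'
#' Makes `pair: <name>` available in run configurations. The constructor
#' receives the `params` list (and the system `start` tag, if any) and must
#' return a [surface_pair()] carrying template geometry and masses.
#'
#' @param name Registry name.
#' @param constructor `function(params, start)` returning a
#'   [surface_pair()].
#' @return `name`, invisibly.
#' @export
register_surface_pair <- function(name, constructor) {
  stopifnot(is.character(name), is.function(constructor))
  assign(name, constructor, envir = .pair_registry)
  invisible(name)
}

.resolve_pair <- function(name, params, start = NULL) {
  ctors <- .builtin_pairs()
  ctor <- if (exists(name, envir = .pair_registry, inherits = FALSE)) {
    get(name, envir = .pair_registry)
  } else ctors[[name]]
  if (is.null(ctor)) {
    rlang::abort(sprintf("unknown surface pair '%s' (built-ins: %s)", name,
                         paste(names(ctors), collapse = ", ")),
                 class = "rpdyn_config_error")
  }
  ctor(params %||% list(), start)
}

#' Read and validate a run configuration
#'
#' @param path Path to a YAML run configuration (see
#'   [write_demo_config()] for a complete example).
#' @return A validated list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg, where = path)
}

#' @rdname read_run_config
#' @param config A configuration list (as parsed from YAML).
#' @param where Label used in error messages.
#' @export
validate_run_config <- function(config, where = "config") {
  bad_key <- function(keys, allowed, block) {
    unknown <- setdiff(keys, allowed)
    if (length(unknown) > 0L) {
      rlang::abort(sprintf("%s: unknown key '%s' in block '%s'",
                           where, unknown[1], block),
                   class = "rpdyn_config_error")
    }
  }
  bad_key(names(config), names(.config_schema), "<top level>")
  for (block in c("system", "surfaces", "sampler", "dynamics", "analysis")) {
    if (!is.null(config[[block]])) {
      bad_key(names(config[[block]]), .config_schema[[block]], block)
    }
  }
  if (is.null(config$schema) || !identical(config$schema, "rpdyn/1")) {
    rlang::abort(sprintf("%s: missing or unsupported schema id (need 'rpdyn/1')",
                         where), class = "rpdyn_config_error")
  }
  if (is.null(config$surfaces$pair)) {
    rlang::abort(sprintf("%s: surfaces$pair is required", where),
                 class = "rpdyn_config_error")
  }
  config$seed <- as.integer(config$seed %||% 1L)
  structure(config, class = "run_config")
}

#' Write the demo run configuration
#'
#' Emits a complete, commented example configuration for the four-atom
#' torsional toy system with the production-style sampling conditions
#' scaled to desk size.
#'
#' @param path Output path.
#' @param n_steps,n_trajectories Scale knobs for the demo.
#' @return `path`, invisibly.
#' @export
write_demo_config <- function(path, n_steps = 4000L, n_trajectories = 25L) {
  cfg <- list(
    schema = "rpdyn/1",
    seed = 1L,
    output_dir = "rpdyn-run",
    system = list(start = "trans"),
    surfaces = list(pair = "toy_torsional"),
    sampler = list(temperature = 300, n_beads = 32L, dt = 0.3,
                   n_steps = as.integer(n_steps), sample_stride = 10L,
                   force_mode = "centroid_taylor"),
    dynamics = list(dt = 0.3, max_steps = 500L,
                    n_trajectories = as.integer(n_trajectories),
                    stop_rule = "distance", r_diss = 8),
    analysis = list(fragments_a = c(1L, 2L), fragments_b = c(3L, 4L),
                    dihedral = c(1L, 2L, 3L, 4L),
                    eb_bin_width = 0.02, ek_bin_width = 0.05)
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}
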