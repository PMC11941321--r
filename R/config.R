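#' Default run configuration
#'
#' The full nested configuration with every model, pulse, dynamics, sweep,
#' fit and synthetic-experiment setting at its default. The base image
#' energy defaults to `E = 0.8 / (4 pi)` so that the unperturbed temporal
#' frequency `4 pi E / h` is 0.8, the exposure-frequency scale used by the
#' reference sweeps.
#'
#' @return A nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    model = list(h = 1, m = 1, a = 2, U0 = 5, E = 0.8 / (4 * pi), A = 1,
                 beta = 0, omega0 = 1, dialect = "cosine",
                 regime = "internal"),
    pulse = list(H = 0.5, T = 3, omega_d = 0.8, t0 = 0,
                 clamp_policy = "clamp_zero"),
    dynamics = list(x0 = 0, v0 = 0.5, dt = 0.01, t_end = 20,
                    delta_width = NA, delta_on = TRUE, mirror_delta = FALSE,
                    B = 0, C = 0),
    sweep = list(swept = "omega_d", grid_lo = 0.2, grid_hi = 2, grid_n = 10L,
                 t_lo = 0, t_hi = 20, t_n = 201L, x_eval = NA,
                 slice_at = 0.8),
    fit = list(params = c("E", "A", "H", "T", "omega_d"),
               bounds = list(E = c(0.01, 0.3), A = c(0.5, 4), H = c(0, 0.4),
                             T = c(1, 9), omega_d = c(0.1, 2.5)),
               method = "grid", n_points_per_axis = 7L, shrink_factor = 0.5,
               n_refinements = 6L, n_starts = 5L, true_theta = NA),
    synth = list(n_subjects = 227L, scale_min = 1, scale_max = 9, w_p = 0.5,
                 w_s = 0.5, lambda_neg = 1.5, noise_sd = 1,
                 nominal_positive = 8, nominal_negative = 2,
                 target = "experiment")
  )
}

# internal: recursive unknown-key check against the defaults
check_known_keys <- function(cfg, ref, path = "") {
  bad <- setdiff(names(cfg), names(ref))
  if (length(bad)) {
    stop("unknown config key", if (length(bad) > 1) "s", ": ",
         paste0(path, bad, collapse = ", "), call. = FALSE)
  }
  for (nm in names(cfg)) {
    if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]])) && is.list(cfg[[nm]])) {
      check_known_keys(cfg[[nm]], ref[[nm]], paste0(path, nm, "$"))
    }
  }
  invisible(TRUE)
}

# internal: fill missing keys from defaults, one level of nesting
fill_defaults <- function(cfg, ref) {
  for (nm in names(ref)) {
    if (is.null(cfg[[nm]])) {
      cfg[[nm]] <- ref[[nm]]
    } else if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]]))) {
      for (k in names(ref[[nm]])) {
        if (is.null(cfg[[nm]][[k]])) cfg[[nm]][[k]] <- ref[[nm]][[k]]
      }
    }
  }
  cfg[names(ref)]
}

#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON, a YAML subset) key-value file, rejects unknown
#' keys, fills defaults for missing ones and validates every constraint by
#' constructing the corresponding model objects. An empty file yields the
#' full default configuration.
#'
#' @param path Path to the configuration file.
#' @return A validated nested list (see [default_config()]).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  resolve_config(cfg)
}

#' Resolve a partial configuration list
#'
#' The in-memory counterpart of [load_config()]: unknown-key rejection,
#' default filling and validation of a nested list.
#'
#' @param cfg A (possibly partial) nested configuration list.
#' @return A validated full configuration.
#' @export
resolve_config <- function(cfg) {
  ref <- default_config()
  check_known_keys(cfg, ref)
  cfg <- fill_defaults(cfg, ref)
  validate_config(cfg)
  cfg
}

# internal: constraint validation by constructing the model objects
validate_config <- function(cfg) {
  wrap <- function(section, expr) {
    tryCatch(expr, error = function(e) {
      stop("config section '", section, "': ", conditionMessage(e),
           call. = FALSE)
    })
  }
  wrap("model", {
    cc <- model_constants(cfg$model$h, cfg$model$m)
    potential_well(cfg$model$a, cfg$model$U0)
    information_image(cfg$model$E, cfg$model$A, cfg$model$beta,
                      cfg$model$omega0, cc)
    match.arg(cfg$model$dialect, c("cosine", "sine"))
    match.arg(cfg$model$regime, c("internal", "communication"))
  })
  wrap("pulse", {
    influence_pulse(cfg$pulse$H, cfg$pulse$T, cfg$pulse$omega_d, cfg$pulse$t0)
    match.arg(cfg$pulse$clamp_policy, c("clamp_zero", "error"))
  })
  wrap("dynamics", {
    integrator_config(cfg$dynamics$dt, cfg$dynamics$t_end,
                      cfg$dynamics$delta_width, isTRUE(cfg$dynamics$delta_on),
                      isTRUE(cfg$dynamics$mirror_delta), cfg$dynamics$B,
                      cfg$dynamics$C)
    stopifnot(is.finite(cfg$dynamics$x0), is.finite(cfg$dynamics$v0))
  })
  wrap("sweep", {
    match.arg(cfg$sweep$swept, c("omega_d", "H"))
    stopifnot(cfg$sweep$grid_lo < cfg$sweep$grid_hi, cfg$sweep$grid_n >= 1,
              cfg$sweep$t_lo < cfg$sweep$t_hi, cfg$sweep$t_n >= 1)
  })
  wrap("fit", {
    stopifnot(all(cfg$fit$params %in% names(cfg$fit$bounds)),
              cfg$fit$method %in% c("lsq", "grid"))
    grid_config(cfg$fit$n_points_per_axis, cfg$fit$shrink_factor,
                cfg$fit$n_refinements, cfg$fit$n_starts, cfg$seed)
  })
  wrap("synth", {
    experiment_config(cfg$synth$n_subjects, cfg$synth$scale_min,
                      cfg$synth$scale_max, cfg$synth$w_p, cfg$synth$w_s,
                      cfg$synth$lambda_neg, cfg$synth$noise_sd,
                      cfg$synth$nominal_positive, cfg$synth$nominal_negative,
                      cfg$seed)
    match.arg(cfg$synth$target, c("experiment", "model"))
  })
  invisible(cfg)
}

#' Save a configuration to YAML
#'
#' `load_config(save_config(cfg, path))` round-trips to an identical
#' configuration.
#'
#' @param cfg A configuration list.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path, precision = 15L)
  invisible(path)
}
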