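#' Specification of a parameter sweep of the perturbed state
#'
#' Describes a grid of values for one pulse parameter (`omega_d` or `H`),
#' a time grid, and a fixed evaluation position, together with the base
#' image and pulse. Sweeping reproduces the structure of the simulation
#' figures: state-function time courses as the exposure frequency or
#' amplitude varies.
#'
#' @param swept `"omega_d"` or `"H"`: the pulse parameter swept along axis 1.
#' @param grid Strictly increasing, non-empty values of the swept parameter.
#' @param t_grid Strictly increasing, non-empty evaluation times (axis 2).
#' @param x_eval Evaluation position. A point strictly inside the well where
#'   the spatial factor is nontrivial; `0.25 * a` is a sensible choice.
#' @param image An [information_image()].
#' @param pulse An [influence_pulse()] providing the non-swept pulse
#'   parameters.
#' @param policy Clamp policy passed to [perturbed_state()].
#' @return An object of class `cogwell_sweep_spec`.
#' @export
sweep_spec <- function(swept = c("omega_d", "H"), grid, t_grid, x_eval,
                       image, pulse, policy = "clamp_zero") {
  swept <- match.arg(swept)
  stopifnot(inherits(image, "cogwell_image"), inherits(pulse, "cogwell_pulse"),
            is.numeric(grid), is.numeric(t_grid),
            is.numeric(x_eval), length(x_eval) == 1L)
  if (length(grid) == 0L || (length(grid) > 1L && any(diff(grid) <= 0))) {
    stop("'grid' must be non-empty and strictly increasing", call. = FALSE)
  }
  if (length(t_grid) == 0L || (length(t_grid) > 1L && any(diff(t_grid) <= 0))) {
    stop("'t_grid' must be non-empty and strictly increasing", call. = FALSE)
  }
  structure(list(swept = swept, grid = grid, t_grid = t_grid, x_eval = x_eval,
                 image = image, pulse = pulse, policy = policy),
            class = "cogwell_sweep_spec")
}

#' Evaluate a parameter sweep into a response surface
#'
#' For each value of the swept parameter, evaluates the perturbed state at
#' `x_eval` over the full time grid: `values[i, j]` is the state with the
#' swept parameter set to `grid[i]` at time `t_grid[j]`. Pure evaluation —
#' no interpolation — so refining the time grid leaves existing samples
#' unchanged.
#'
#' @param spec A [sweep_spec()].
#' @return An object of class `cogwell_surface`: list with `axis1` (swept
#'   values), `axis2` (times), `swept`, and the `values` matrix.
#' @export
#' @examples
#' ii <- information_image(E = 0.2, A = 1)
#' p <- influence_pulse(H = 0.5, T = 3, omega_d = 0.8)
#' sp <- sweep_spec("H", grid = c(0, 0.5, 1), t_grid = seq(0, 10, 0.5),
#'                  x_eval = 0.5, image = ii, pulse = p)
#' s <- sweep_surface(sp)
#' dim(s$values)
sweep_surface <- function(spec) {
  stopifnot(inherits(spec, "cogwell_sweep_spec"))
  vals <- matrix(NA_real_, nrow = length(spec$grid),
                 ncol = length(spec$t_grid))
  for (i in seq_along(spec$grid)) {
    p <- spec$pulse
    p[[spec$swept]] <- spec$grid[i]
    vals[i, ] <- perturbed_state(spec$x_eval, spec$t_grid, spec$image, p,
                                 policy = spec$policy)
  }
  if (any(!is.finite(vals))) {
    stop("non-finite surface values", call. = FALSE)
  }
  structure(list(axis1 = spec$grid, axis2 = spec$t_grid, swept = spec$swept,
                 x_eval = spec$x_eval, values = vals),
            class = "cogwell_surface")
}

#' @export
print.cogwell_surface <- function(x, ...) {
  cat("Response surface:", length(x$axis1), "x", length(x$axis2),
      "(", x$swept, "x time ) at x_eval =", x$x_eval, "\n")
  invisible(x)
}

#' Univariate slice of a response surface
#'
#' Cuts the surface along one axis at the grid point nearest `at`
#' (nearest-grid-point, not interpolated, so slices are exactly
#' reproducible). The resulting curve is the model-side input handed to
#' the fitting procedures.
#'
#' @param surface A `cogwell_surface`.
#' @param axis `"swept"`: fix the swept parameter, vary time;
#'   `"time"`: fix time, vary the swept parameter.
#' @param at Coordinate on the fixed axis; must lie within its range.
#' @return A data.frame with columns `coordinate` and `response`.
#' @export
slice_1d <- function(surface, axis = c("swept", "time"), at) {
  axis <- match.arg(axis)
  stopifnot(inherits(surface, "cogwell_surface"), is.numeric(at),
            length(at) == 1L)
  fixed <- if (axis == "swept") surface$axis1 else surface$axis2
  if (at < min(fixed) || at > max(fixed)) {
    stop("range error: 'at' = ", at, " outside the ", axis, " axis range [",
         min(fixed), ", ", max(fixed), "]", call. = FALSE)
  }
  i <- which.min(abs(fixed - at))
  if (axis == "swept") {
    data.frame(coordinate = surface$axis2, response = surface$values[i, ])
  } else {
    data.frame(coordinate = surface$axis1, response = surface$values[, i])
  }
}

#' Write a response surface to CSV
#'
#' Matrix layout with the time grid as the header row and the swept values
#' as the first column.
#'
#' @param surface A `cogwell_surface`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_surface <- function(surface, path) {
  df <- as.data.frame(surface$values)
  names(df) <- paste0("t_", format(surface$axis2, trim = TRUE))
  df <- cbind(stats::setNames(data.frame(surface$axis1), surface$swept), df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a slice curve to CSV
#'
#' Two columns: `coordinate`, `response`.
#'
#' @param slice A data.frame from [slice_1d()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_slice <- function(slice, path) {
  utils::write.csv(slice, path, row.names = FALSE)
  invisible(path)
}
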