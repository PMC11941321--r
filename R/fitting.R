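#' Define a least-squares fitting problem
#'
#' Pairs an observed response curve with a parameterized model curve. The
#' model is a function `model(theta, s)` returning the model response at the
#' observed coordinates `s` for a named parameter vector `theta`. When
#' `"scale"` is among the parameter names, a single global scaling factor
#' multiplies the model curve inside the objective (and is not passed to the
#' model); note that amplitude-like parameters and `scale` then enter
#' multiplicatively, so one of the two should be fixed.
#'
#' @param observed A data.frame (or 2-column object) whose first two columns
#'   are the coordinate `s` and the response `y`; at least 2 points.
#' @param model `function(theta, s)` -> numeric vector of length `length(s)`.
#' @param theta_names Ordered parameter names, a subset of
#'   `c("E", "A", "H", "T", "omega_d", "x_eval", "scale")` or any names the
#'   model understands.
#' @param bounds Named list of closed intervals `c(lo, hi)`, one per
#'   parameter, all non-degenerate; `scale` bounds must be positive.
#' @return An object of class `cogwell_fit_problem`.
#' @export
fit_problem <- function(observed, model, theta_names, bounds) {
  observed <- as.data.frame(observed)
  stopifnot(ncol(observed) >= 2L, is.function(model),
            is.character(theta_names), length(theta_names) >= 1L)
  s <- as.numeric(observed[[1L]])
  y <- as.numeric(observed[[2L]])
  if (length(s) < 2L) stop("need >= 2 observation points", call. = FALSE)
  if (!all(theta_names %in% names(bounds))) {
    stop("bounds missing for: ",
         paste(setdiff(theta_names, names(bounds)), collapse = ", "),
         call. = FALSE)
  }
  bmat <- vapply(theta_names, function(nm) as.numeric(bounds[[nm]]),
                 numeric(2L))
  if (any(bmat[2L, ] <= bmat[1L, ])) {
    stop("degenerate bounds: every interval needs lo < hi", call. = FALSE)
  }
  if ("scale" %in% theta_names && bmat[1L, match("scale", theta_names)] <= 0) {
    stop("'scale' bounds must be positive", call. = FALSE)
  }
  structure(list(s = s, y = y, model = model, theta_names = theta_names,
                 lower = stats::setNames(bmat[1L, ], theta_names),
                 upper = stats::setNames(bmat[2L, ], theta_names)),
            class = "cogwell_fit_problem")
}

#' Sum-of-squares objective
#'
#' `sum((scale * model(s; theta) - y)^2)`, with `scale` fixed to 1 when it is
#' not a fitted parameter. The parameter vector must lie within the
#' problem's bounds.
#'
#' @param theta Named (or positionally ordered) numeric parameter vector.
#' @param problem A [fit_problem()].
#' @return Non-negative objective value.
#' @export
fit_objective <- function(theta, problem) {
  stopifnot(inherits(problem, "cogwell_fit_problem"))
  theta <- stats::setNames(as.numeric(theta), problem$theta_names)
  if (any(theta < problem$lower - 1e-12) || any(theta > problem$upper + 1e-12)) {
    stop("theta outside bounds", call. = FALSE)
  }
  eval_sse(theta, problem)
}

# internal: SSE without the bounds check (grid points are in bounds by
# construction; local search clamps instead)
eval_sse <- function(theta, problem) {
  scale <- 1
  if ("scale" %in% problem$theta_names) {
    scale <- theta[["scale"]]
    theta <- theta[setdiff(problem$theta_names, "scale")]
  }
  # clamp warnings from deliberately explored E + D < 0 corners of the
  # parameter space would fire once per grid point; keep the search quiet
  m <- tryCatch(suppressWarnings(problem$model(theta, problem$s)),
                error = function(e) {
    stop("model evaluation failed at theta = (",
         paste(signif(theta, 6), collapse = ", "), "): ",
         conditionMessage(e), call. = FALSE)
  })
  sum((scale * m - problem$y)^2)
}

# internal: assemble a fit result, recomputing the invariant fields
fit_result <- function(theta_hat, objective, trace, n_evals, converged,
                       seed = NA_integer_) {
  structure(list(theta_hat = theta_hat, objective = objective, trace = trace,
                 n_evals = n_evals, converged = converged, seed = seed),
            class = "cogwell_fit")
}

#' @export
print.cogwell_fit <- function(x, ...) {
  cat("Least-squares fit: objective =", format(x$objective, digits = 6),
      "(", x$n_evals, "evaluations,",
      if (isTRUE(x$converged)) "converged" else "not converged", ")\n")
  cat("  theta_hat:\n")
  print(round(x$theta_hat, 6))
  invisible(x)
}

#' Local least-squares fit by derivative-free descent
#'
#' Nelder-Mead descent from a starting point, with box constraints enforced
#' by clamping proposals to the bounds before evaluation. The returned
#' point is the best point ever evaluated, so the result's objective never
#' exceeds the objective at `init`. Deterministic given `init`.
#'
#' @param problem A [fit_problem()].
#' @param init Named or ordered numeric starting values, within bounds.
#' @param max_evals Evaluation budget (default 2000). If exhausted before
#'   the simplex diameter falls below tolerance the result is flagged
#'   `converged = FALSE` (still valid).
#' @param reltol Relative convergence tolerance (default 1e-8).
#' @return A `cogwell_fit` result: `theta_hat`, `objective`, the evaluation
#'   `trace` (one row per evaluation), `n_evals`, `converged`.
#' @export
fit_local <- function(problem, init, max_evals = 2000, reltol = 1e-8) {
  stopifnot(inherits(problem, "cogwell_fit_problem"))
  init <- stats::setNames(as.numeric(init), problem$theta_names)
  if (any(init < problem$lower) || any(init > problem$upper)) {
    stop("init outside bounds", call. = FALSE)
  }
  env <- new.env()
  env$thetas <- list()
  env$objs <- numeric(0)
  fn <- function(par) {
    par <- pmin(pmax(par, problem$lower), problem$upper)
    val <- eval_sse(stats::setNames(par, problem$theta_names), problem)
    env$thetas[[length(env$thetas) + 1L]] <- par
    env$objs <- c(env$objs, val)
    val
  }
  p <- length(init)
  if (p == 1L) {
    # Nelder-Mead degenerates in 1-D; golden-section via optimize
    fn(init)
    stats::optimize(function(z) fn(z), lower = problem$lower,
                    upper = problem$upper, tol = reltol)
    conv <- TRUE
  } else {
    opt <- stats::optim(init, fn, method = "Nelder-Mead",
                        control = list(maxit = max_evals, reltol = reltol))
    conv <- opt$convergence == 0L
  }
  best <- which.min(env$objs)
  trace <- as.data.frame(do.call(rbind, env$thetas))
  names(trace) <- problem$theta_names
  trace$objective <- env$objs
  fit_result(theta_hat = stats::setNames(env$thetas[[best]],
                                         problem$theta_names),
             objective = env$objs[best], trace = trace,
             n_evals = length(env$objs), converged = conv)
}

#' Configuration for the adaptive grid search
#'
#' Controls the multi-start search on a discrete parameter grid with
#' dynamically shrinking steps: each start evaluates a full Cartesian grid
#' over its box, re-centres a box shrunk by `shrink_factor` per axis on the
#' best point, and repeats `n_refinements` times.
#'
#' @param n_points_per_axis Grid points per parameter axis, >= 3 (default 7).
#' @param shrink_factor Box shrink per refinement, in (0, 1) (default 0.5).
#' @param n_refinements Number of shrink-and-recentre rounds (default 6).
#' @param n_starts Number of starts (default 5). The first start always
#'   covers the full bounds; subsequent starts use random boxes of half the
#'   bounds span centred at seeded uniform draws (clipped into bounds).
#' @param seed Integer seed for the random starts (default 1).
#' @return An object of class `cogwell_grid_config`.
#' @export
grid_config <- function(n_points_per_axis = 7, shrink_factor = 0.5,
                        n_refinements = 6, n_starts = 5, seed = 1) {
  stopifnot(n_points_per_axis >= 3, shrink_factor > 0, shrink_factor < 1,
            n_refinements >= 0, n_starts >= 1)
  structure(list(n_points_per_axis = as.integer(n_points_per_axis),
                 shrink_factor = shrink_factor,
                 n_refinements = as.integer(n_refinements),
                 n_starts = as.integer(n_starts), seed = as.integer(seed)),
            class = "cogwell_grid_config")
}

#' Adaptive discrete grid search with random multi-start
#'
#' The numerical parameter-selection procedure: for each start, the
#' objective is evaluated on the full Cartesian grid over the start's box;
#' the box is then shrunk by `shrink_factor` per axis, re-centred on the
#' best grid point (clipped to stay within bounds) and re-evaluated,
#' `n_refinements` times. The overall best point across all starts and
#' refinements is returned. Ties on a grid break to the lowest
#' lexicographic index; results are reproducible given the seed.
#'
#' With `n_starts = 1, n_refinements = 0` this is exactly the argmin over
#' the single full-bounds coarse grid.
#'
#' @param problem A [fit_problem()].
#' @param config A [grid_config()].
#' @return A `cogwell_fit` result. The `trace` records the best
#'   (theta, objective) of every evaluated grid (start x refinement);
#'   `n_evals` counts every objective evaluation.
#' @export
fit_grid_adaptive <- function(problem, config = grid_config()) {
  stopifnot(inherits(problem, "cogwell_fit_problem"),
            inherits(config, "cogwell_grid_config"))
  lower <- problem$lower
  upper <- problem$upper
  span <- upper - lower
  p <- length(lower)
  npts <- config$n_points_per_axis

  # seeded start centres, drawn up-front so the draw count is fixed
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)
  centres <- matrix(stats::runif((config$n_starts) * p, lower, upper),
                    ncol = p, byrow = TRUE)

  eval_grid <- function(lo, hi) {
    axes <- lapply(seq_len(p), function(j) seq(lo[j], hi[j], length.out = npts))
    grid <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
    objs <- apply(grid, 1L, function(th)
      eval_sse(stats::setNames(th, problem$theta_names), problem))
    b <- which.min(objs)  # first minimum: lowest lexicographic index
    list(theta = grid[b, ], obj = objs[b], n = nrow(grid))
  }

  clip_box <- function(centre, half) {
    lo <- pmax(centre - half, lower)
    hi <- pmin(centre + half, upper)
    # keep the box width by shifting when clipped against one side
    lo <- pmin(lo, upper - 2 * half)
    hi <- pmax(hi, lower + 2 * half)
    list(lo = pmax(lo, lower), hi = pmin(hi, upper))
  }

  best_theta <- NULL
  best_obj <- Inf
  n_evals <- 0L
  trace <- list()
  for (s in seq_len(config$n_starts)) {
    if (s == 1L) {
      lo <- lower
      hi <- upper
    } else {
      box <- clip_box(centres[s, ], span / 4)
      lo <- box$lo
      hi <- box$hi
    }
    for (r in 0:config$n_refinements) {
      if (r > 0L) {
        half <- (hi - lo) / 2 * config$shrink_factor
        box <- clip_box(centre, half)
        lo <- box$lo
        hi <- box$hi
      }
      g <- eval_grid(lo, hi)
      n_evals <- n_evals + g$n
      centre <- g$theta
      trace[[length(trace) + 1L]] <- c(g$theta, objective = g$obj)
      if (g$obj < best_obj) {
        best_obj <- g$obj
        best_theta <- g$theta
      }
    }
  }
  trace <- as.data.frame(do.call(rbind, trace))
  names(trace) <- c(problem$theta_names, "objective")
  fit_result(theta_hat = stats::setNames(best_theta, problem$theta_names),
             objective = best_obj, trace = trace, n_evals = n_evals,
             converged = TRUE, seed = config$seed)
}

#' Final grid spacing of an adaptive search
#'
#' Per-axis spacing of the most refined grid of the first (full-bounds)
#' start: `span * shrink^n_refinements / (n_points - 1)`. Useful as the
#' resolution against which parameter-recovery error is judged.
#'
#' @param problem A [fit_problem()].
#' @param config A [grid_config()].
#' @return Named numeric vector of spacings.
#' @export
final_grid_spacing <- function(problem, config = grid_config()) {
  (problem$upper - problem$lower) * config$shrink_factor^config$n_refinements /
    (config$n_points_per_axis - 1)
}

#' Model-curve factory for fitting the perturbed state to a rating curve
#'
#' Builds the `model(theta, s)` function used by the fitting procedures:
#' the observed abscissa is treated directly as the time coordinate of a
#' univariate slice of the perturbed state at position `x_eval`, offset by
#' a constant (e.g. the rating-scale midpoint). Parameters named among
#' `E, A, H, T, omega_d, x_eval` override the base image/pulse; anything
#' else (including `scale`) is handled by the objective, not here.
#'
#' @param image Base [information_image()] supplying non-fitted image
#'   parameters.
#' @param pulse Base [influence_pulse()] supplying non-fitted pulse
#'   parameters.
#' @param x_eval Default evaluation position (overridden when `"x_eval"` is
#'   fitted).
#' @param offset Constant added to the curve (default 0).
#' @param policy Clamp policy for [perturbed_state()].
#' @return `function(theta, s)`.
#' @export
slice_model <- function(image, pulse, x_eval, offset = 0,
                        policy = "clamp_zero") {
  stopifnot(inherits(image, "cogwell_image"), inherits(pulse, "cogwell_pulse"))
  force(x_eval); force(offset); force(policy)
  function(theta, s) {
    im <- image
    pu <- pulse
    xe <- x_eval
    for (nm in names(theta)) {
      val <- theta[[nm]]
      switch(nm,
             E = , A = { im[[nm]] <- val },
             H = , T = , omega_d = { pu[[nm]] <- val },
             x_eval = { xe <- val },
             stop("unknown model parameter: ", nm, call. = FALSE))
    }
    if (im$E < 0 || pu$T <= 0) {
      stop("invalid parameter value (E < 0 or T <= 0)", call. = FALSE)
    }
    offset + perturbed_state(xe, s, im, pu, policy = policy)
  }
}
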