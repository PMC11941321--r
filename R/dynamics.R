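#' Integrator configuration for the self-oscillatory equations of motion
#'
#' Fixed-step classical Runge-Kutta (RK4) settings, plus the regularization of
#' the Dirac barrier impulse. The delta term is replaced by a unit-integral
#' Gaussian bump in the delta's argument `u = 2x/a - 1`; `delta_width` is the
#' bump's standard deviation expressed in position units (default `a/100`,
#' resolved against the well at simulation time when left `NULL`).
#'
#' @param dt Step size, > 0.
#' @param t_end Integration horizon, > 0.
#' @param delta_width Regularization width sigma_delta in position units;
#'   `NULL` means `a/100` of the simulated well.
#' @param delta_on Include the barrier impulse term (default `TRUE`).
#' @param mirror_delta Also place an impulse at the left wall `2x/a + 1 = 0`
#'   (default `FALSE`: only the right-wall term of the printed equation).
#' @param B,C Surviving Zone-2 forcing coefficients for the left and right
#'   sides respectively (default 0: internal regime, no outside forcing).
#' @return An object of class `cogwell_integrator_config`.
#' @export
integrator_config <- function(dt, t_end, delta_width = NULL, delta_on = TRUE,
                              mirror_delta = FALSE, B = 0, C = 0) {
  stopifnot(is.numeric(dt), length(dt) == 1L, is.numeric(t_end),
            length(t_end) == 1L, is.logical(delta_on), is.logical(mirror_delta),
            is.numeric(B), is.numeric(C))
  if (!is.finite(dt) || dt <= 0) stop("'dt' must be > 0", call. = FALSE)
  if (!is.finite(t_end) || t_end <= 0) stop("'t_end' must be > 0", call. = FALSE)
  if (is.null(delta_width) || isTRUE(is.na(delta_width))) {
    delta_width <- NULL  # resolved to a/100 at simulation time
  } else if (!is.finite(delta_width) || delta_width <= 0) {
    stop("'delta_width' must be > 0", call. = FALSE)
  }
  structure(list(dt = dt, t_end = t_end, delta_width = delta_width,
                 delta_on = delta_on, mirror_delta = mirror_delta,
                 B = B, C = C),
            class = "cogwell_integrator_config")
}

# internal: Gaussian bump of unit integral in the delta argument u = 2x/a - 1.
# sigma_x is the width in position units; in u units sigma_u = 2 sigma_x / a.
delta_bump <- function(u, sigma_u) {
  exp(-u^2 / (2 * sigma_u^2)) / (sigma_u * sqrt(2 * pi))
}

# internal: the regularized barrier impulse. The delta sits exactly at the
# wall, so its regularization straddles both zones; it is therefore a wall
# term shared by both sides of the dispatch, keeping the force continuous
# at the crossing (the point of regularizing in the first place).
barrier_force <- function(x, well, config) {
  if (!config$delta_on) return(0 * x)
  sigma_x <- if (is.null(config$delta_width)) well$a / 100 else config$delta_width
  sigma_u <- 2 * sigma_x / well$a
  f <- (2 * well$U0 / well$a) * delta_bump(2 * x / well$a - 1, sigma_u)
  if (config$mirror_delta) {
    f <- f + (2 * well$U0 / well$a) * delta_bump(2 * x / well$a + 1, sigma_u)
  }
  f
}

#' Force on the image inside the well (Zone 1)
#'
#' `F = A omega0 sin(omega0 x) cos(omega_q t + beta) + (2 U0 / a) g(2x/a - 1)`
#' where `g` is the regularized Dirac bump at the right wall (and, if
#' `mirror_delta`, its mirror at the left wall). Integrating the impulse term
#' across the barrier in `x` yields exactly `U0` (Jacobian `a/2` of the delta
#' argument).
#'
#' @param x Position(s) (the zone dispatch is the integrator's job, not
#'   checked here).
#' @param t Time(s).
#' @param image An [information_image()].
#' @param well A [potential_well()].
#' @param config An [integrator_config()].
#' @return Force value(s).
#' @export
force_zone1 <- function(x, t, image, well, config) {
  image$A * image$omega0 * sin(image$omega0 * x) *
    cos(omega_q(image) * t + image$beta) + barrier_force(x, well, config)
}

#' Force on the image outside the well (Zone 2)
#'
#' The evanescent-tail forcing with the side's surviving coefficient:
#' `C omega_q |v2| exp(-omega_q |v2| x) cos(omega_q t + beta)` to the right of
#' the well, and the mirrored `B`-coefficient form (decaying towards
#' `-infinity`) to the left.
#'
#' @inheritParams force_zone1
#' @param side `"right"` (x >= a/2, coefficient C) or `"left"` (x <= -a/2,
#'   coefficient B).
#' @param coef The side's surviving coefficient.
#' @return Force value(s); decays exponentially away from the well.
#' @export
force_zone2 <- function(x, t, image, well, side = c("right", "left"),
                        coef = 1) {
  side <- match.arg(side)
  kappa <- omega_q(image) * evanescent_speed(image, well)
  env <- if (side == "right") exp(-kappa * x) else exp(kappa * x)
  coef * kappa * env * cos(omega_q(image) * t + image$beta)
}

# internal: precomputed fast acceleration closure used by the integrator.
# Same formulas as force_zone1/force_zone2/barrier_force (asserted by a
# test), with the constants hoisted out of the time loop.
make_accel <- function(image, well, config) {
  wq <- 4 * pi * image$E / image$h
  beta <- image$beta
  Aw0 <- image$A * image$omega0
  w0 <- image$omega0
  m <- image$m
  a2 <- well$a / 2
  B <- config$B
  C <- config$C
  kappa <- if (B != 0 || C != 0) wq * evanescent_speed(image, well) else 0
  delta_on <- isTRUE(config$delta_on)
  sigma_x <- if (is.null(config$delta_width)) well$a / 100 else config$delta_width
  sigma_u <- 2 * sigma_x / well$a
  dcoef <- (2 * well$U0 / well$a) / (sigma_u * sqrt(2 * pi))
  inv2s2 <- 1 / (2 * sigma_u^2)
  mirror <- isTRUE(config$mirror_delta)
  function(x, t) {
    f <- if (abs(x) < a2) {
      Aw0 * sin(w0 * x) * cos(wq * t + beta)
    } else if (x > 0) {
      C * kappa * exp(-kappa * x) * cos(wq * t + beta)
    } else {
      B * kappa * exp(kappa * x) * cos(wq * t + beta)
    }
    if (delta_on) {
      u <- 2 * x / well$a - 1
      f <- f + dcoef * exp(-u * u * inv2s2)
      if (mirror) {
        up <- 2 * x / well$a + 1
        f <- f + dcoef * exp(-up * up * inv2s2)
      }
    }
    f / m
  }
}

# internal: acceleration with zone dispatch by current position. The smooth
# zone forcings are partitioned; the regularized wall impulse (already part
# of force_zone1) is added outside too so the force stays continuous at a
# crossing.
dispatch_accel <- function(x, t, image, well, config) {
  if (abs(x) < well$a / 2) {
    force_zone1(x, t, image, well, config) / image$m
  } else if (x > 0) {
    (force_zone2(x, t, image, well, "right", config$C) +
       barrier_force(x, well, config)) / image$m
  } else {
    (force_zone2(x, t, image, well, "left", config$B) +
       barrier_force(x, well, config)) / image$m
  }
}

#' Simulate the self-oscillatory motion of an information image
#'
#' Fixed-step 4th-order Runge-Kutta integration of the piecewise equation of
#' motion: the Zone-1 forcing with the regularized barrier impulse inside the
#' well and the evanescent Zone-2 forcing outside, selected by the current
#' position at every stage evaluation. Every step is recorded.
#'
#' If a step crosses a wall fast enough that the impulse bump spans fewer
#' than 10 steps (`sigma_delta / |v| < 10 dt`), a warning notes that the
#' impulse is under-resolved.
#'
#' @param image An [information_image()].
#' @param well A [potential_well()].
#' @param x0,v0 Initial position and velocity (finite).
#' @param config An [integrator_config()].
#' @return An object of class `cogwell_trajectory`: a list with `times`,
#'   `x`, `v`, `zone` (1 or 2) and the well/image used. Convert with
#'   [as.data.frame()] or scan with [detect_exit()].
#' @export
#' @examples
#' w <- potential_well(a = 2, U0 = 5)
#' ii <- information_image(E = 0.5, A = 0.3)
#' tr <- simulate_motion(ii, w, x0 = 0, v0 = 0.5,
#'                       integrator_config(dt = 0.01, t_end = 5))
#' head(as.data.frame(tr))
simulate_motion <- function(image, well, x0, v0, config) {
  stopifnot(inherits(image, "cogwell_image"), inherits(well, "cogwell_well"),
            inherits(config, "cogwell_integrator_config"),
            is.finite(x0), is.finite(v0))
  dt <- config$dt
  n <- floor(config$t_end / dt + 1e-9)
  times <- dt * (0:n)
  xs <- numeric(n + 1L)
  vs <- numeric(n + 1L)
  xs[1L] <- x0
  vs[1L] <- v0
  sigma_x <- if (is.null(config$delta_width)) well$a / 100 else config$delta_width
  warned <- FALSE
  acc <- make_accel(image, well, config)
  for (i in seq_len(n)) {
    t <- times[i]
    x <- xs[i]
    v <- vs[i]
    k1x <- v;                 k1v <- acc(x, t)
    k2x <- v + dt / 2 * k1v;  k2v <- acc(x + dt / 2 * k1x, t + dt / 2)
    k3x <- v + dt / 2 * k2v;  k3v <- acc(x + dt / 2 * k2x, t + dt / 2)
    k4x <- v + dt * k3v;      k4v <- acc(x + dt * k3x, t + dt)
    xs[i + 1L] <- x + dt / 6 * (k1x + 2 * k2x + 2 * k3x + k4x)
    vs[i + 1L] <- v + dt / 6 * (k1v + 2 * k2v + 2 * k3v + k4v)
    if (!is.finite(xs[i + 1L]) || !is.finite(vs[i + 1L])) {
      stop("divergence: non-finite state at t = ", times[i + 1L], call. = FALSE)
    }
    crossed <- (abs(x) < well$a / 2) != (abs(xs[i + 1L]) < well$a / 2)
    if (crossed && !warned && config$delta_on) {
      speed <- max(abs(v), abs(vs[i + 1L]))
      if (speed > 0 && sigma_x / speed < 10 * dt) {
        warning("barrier impulse under-resolved at crossing (sigma_delta/|v| ",
                "spans < 10 steps); reduce dt", call. = FALSE)
        warned <- TRUE
      }
    }
  }
  structure(list(times = times, x = xs, v = vs,
                 zone = ifelse(abs(xs) < well$a / 2, 1L, 2L),
                 image = image, well = well, config = config),
            class = "cogwell_trajectory")
}

#' @export
print.cogwell_trajectory <- function(x, ...) {
  cat("Trajectory:", length(x$times), "samples, t in [",
      x$times[1], ",", x$times[length(x$times)], "]\n")
  cat("  final state: x =", x$x[length(x$x)], ", v =", x$v[length(x$v)], "\n")
  invisible(x)
}

#' @export
as.data.frame.cogwell_trajectory <- function(x, ...) {
  ex <- detect_exit(x)
  data.frame(time = x$times, x = x$x, v = x$v, zone = x$zone,
             exit_flag = as.integer(x$times %in% ex$time))
}

#' Detect barrier-exit events along a trajectory
#'
#' An exit event is a recorded sample where the image sits within
#' `sigma_delta` of a wall (`|x| - a/2| <= sigma_delta`) while its kinetic
#' energy `m v^2 / 2` meets or exceeds the barrier `U0` — equivalently its
#' speed reaches the threshold velocity `v_p = sqrt(2 U0 / m)`.
#'
#' @param traj A `cogwell_trajectory` from [simulate_motion()].
#' @param well,image Override the well/image stored in the trajectory
#'   (defaults: those used for the simulation).
#' @return A data.frame with columns `time`, `x`, `kinetic_energy`;
#'   zero rows when the threshold is never met.
#' @export
detect_exit <- function(traj, well = traj$well, image = traj$image) {
  stopifnot(inherits(traj, "cogwell_trajectory"))
  sigma_x <- if (is.null(traj$config$delta_width)) well$a / 100 else
    traj$config$delta_width
  ke <- image$m * traj$v^2 / 2
  near_wall <- abs(abs(traj$x) - well$a / 2) <= sigma_x
  hit <- near_wall & ke >= well$U0
  data.frame(time = traj$times[hit], x = traj$x[hit],
             kinetic_energy = ke[hit])
}

#' Threshold exit velocity
#'
#' The speed at which kinetic energy equals the barrier height:
#' `v_p = sqrt(2 U0 / m)`. Exit requires `v_out = v_p + epsilon` for any
#' positive increment epsilon.
#'
#' @param well A [potential_well()].
#' @param constants A [model_constants()] (for the mass).
#' @return The threshold speed.
#' @export
threshold_velocity <- function(well, constants = model_constants()) {
  stopifnot(inherits(well, "cogwell_well"))
  sqrt(2 * well$U0 / constants$m)
}

#' Write a trajectory to CSV
#'
#' Columns: `time`, `x`, `v`, `zone`, `exit_flag`.
#'
#' @param traj A `cogwell_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
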