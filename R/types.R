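#' Model constants
#'
#' Action-like constant `h` and effective mass `m` of an information image.
#' The model is dimensionless; both default to 1 and only their ratios with
#' the energy scale matter.
#'
#' @param h Action-like constant, > 0.
#' @param m Effective mass of an information image, > 0.
#' @return An object of class `cogwell_constants`.
#' @export
#' @examples
#' model_constants()
model_constants <- function(h = 1, m = 1) {
  stopifnot(is.numeric(h), length(h) == 1L, is.numeric(m), length(m) == 1L)
  if (!is.finite(h) || h <= 0) stop("invalid constants: 'h' must be > 0", call. = FALSE)
  if (!is.finite(m) || m <= 0) stop("invalid constants: 'm' must be > 0", call. = FALSE)
  structure(list(h = h, m = m), class = "cogwell_constants")
}

#' Finite potential well
#'
#' One-dimensional well of width `a` and barrier height `U0`. Zone 1 is the
#' open interval (-a/2, a/2) inside the well; Zone 2 is its complement.
#'
#' @param a Well width, > 0.
#' @param U0 Barrier height, > 0.
#' @return An object of class `cogwell_well`.
#' @export
#' @examples
#' potential_well(a = 2, U0 = 5)
potential_well <- function(a, U0) {
  stopifnot(is.numeric(a), length(a) == 1L, is.numeric(U0), length(U0) == 1L)
  if (!is.finite(a) || a <= 0) stop("invalid well: 'a' must be > 0", call. = FALSE)
  if (!is.finite(U0) || U0 <= 0) stop("invalid well: 'U0' must be > 0", call. = FALSE)
  structure(list(a = a, U0 = U0), class = "cogwell_well")
}

#' Information image
#'
#' The unit of cognitive content in the model: an oscillator with energy
#' (activity level) `E`, oscillation amplitude `A`, phase `beta` and initial
#' frequency `omega0`, living in a potential well. The derived activity
#' frequency is `omega_q(image) = 4*pi*E/h`.
#'
#' @param E Energy / activity level, >= 0.
#' @param A Oscillation amplitude.
#' @param beta Oscillatory motion phase in radians (default 0).
#' @param omega0 Initial frequency of the oscillatory activity (default 1).
#' @param constants A [model_constants()] object supplying `h` and `m`.
#' @return An object of class `cogwell_image`.
#' @export
#' @examples
#' information_image(E = 1, A = 1)
information_image <- function(E, A = 1, beta = 0, omega0 = 1,
                              constants = model_constants()) {
  stopifnot(inherits(constants, "cogwell_constants"),
            is.numeric(E), length(E) == 1L,
            is.numeric(A), length(A) == 1L,
            is.numeric(beta), length(beta) == 1L,
            is.numeric(omega0), length(omega0) == 1L)
  if (!is.finite(E) || E < 0) stop("invalid image: 'E' must be >= 0", call. = FALSE)
  structure(list(E = E, A = A, beta = beta, omega0 = omega0,
                 h = constants$h, m = constants$m),
            class = "cogwell_image")
}

#' External influence pulse
#'
#' Gaussian-windowed cosine representing a second information image or an
#' external information flow: `D(t) = H exp(-4 (t-t0)^2 / T^2) cos(omega_d (t-t0))`.
#'
#' @param H Disturbance amplitude.
#' @param T Characteristic half-life of the exposure, > 0.
#' @param omega_d Natural frequency of the exposure, radians per unit time.
#' @param t0 Pulse centre time (default 0).
#' @return An object of class `cogwell_pulse`.
#' @export
#' @examples
#' influence_pulse(H = 0.5, T = 3, omega_d = 0.8)
influence_pulse <- function(H, T, omega_d, t0 = 0) {
  stopifnot(is.numeric(H), length(H) == 1L, is.numeric(T), length(T) == 1L,
            is.numeric(omega_d), length(omega_d) == 1L,
            is.numeric(t0), length(t0) == 1L)
  if (!is.finite(T) || T <= 0) stop("invalid pulse: 'T' must be > 0", call. = FALSE)
  structure(list(H = H, T = T, omega_d = omega_d, t0 = t0),
            class = "cogwell_pulse")
}

#' @export
print.cogwell_constants <- function(x, ...) {
  cat("Model constants: h =", x$h, ", m =", x$m, "\n")
  invisible(x)
}

#' @export
print.cogwell_well <- function(x, ...) {
  cat("Finite potential well: width a =", x$a,
      ", barrier U0 =", x$U0, "\n")
  cat("  Zone 1 (inside):  (", -x$a / 2, ",", x$a / 2, ")\n")
  invisible(x)
}

#' @export
print.cogwell_image <- function(x, ...) {
  cat("Information image: E =", x$E, ", A =", x$A,
      ", beta =", x$beta, ", omega0 =", x$omega0, "\n")
  cat("  activity frequency omega_q =", 4 * pi * x$E / x$h, "\n")
  invisible(x)
}

#' @export
print.cogwell_pulse <- function(x, ...) {
  cat("Influence pulse: H =", x$H, ", T =", x$T,
      ", omega_d =", x$omega_d, ", t0 =", x$t0, "\n")
  invisible(x)
}

# internal: check that a bound-state evaluation is admissible
check_bound <- function(image, well) {
  if (image$E >= well$U0) {
    stop("unbound image: E >= U0, the image sits above the barrier and has ",
         "no evanescent zone", call. = FALSE)
  }
  invisible(TRUE)
}
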