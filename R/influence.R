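#' Evaluate the influence pulse
#'
#' The interaction function modelling a second information image at the same
#' energy level (or an external information flow):
#' `D(t) = H exp(-4 (t - t0)^2 / T^2) cos(omega_d (t - t0))`.
#' `D` is even about the pulse centre `t0` and bounded by `|H|`.
#'
#' @param pulse An [influence_pulse()].
#' @param t Time(s).
#' @return Influence value(s).
#' @export
#' @examples
#' p <- influence_pulse(H = 1, T = 3, omega_d = 0.8)
#' influence_at(p, 0)  # H at the pulse centre
influence_at <- function(pulse, t) {
  stopifnot(inherits(pulse, "cogwell_pulse"))
  s <- t - pulse$t0
  pulse$H * exp(-4 * s^2 / pulse$T^2) * cos(pulse$omega_d * s)
}

#' Perturbed state function under external influence
#'
#' The final interaction of the base image with the influence pulse: the
#' pulse value `D(t)` shifts the energy inside the spatial wavenumber,
#'
#' `phi(x, t) = A cos(2 pi x sqrt(2 m (E + D(t))) / h) cos(4 pi E t / h)`.
#'
#' The time factor keeps the unperturbed energy `E`. With `H = 0` this
#' reduces exactly to the cosine-dialect inside solution (with `beta = 0`).
#'
#' When `E + D(t) < 0` the wavenumber would turn imaginary; under the default
#' `"clamp_zero"` policy the effective energy is clamped to 0 (the spatial
#' factor becomes 1) with a warning, while `"error"` raises instead. The
#' analytic continuation to unbounded cosh growth is deliberately not
#' implemented: a bounded rating response cannot follow an unbounded state.
#'
#' @param x Position(s).
#' @param t Time(s); recycled against `x`.
#' @param image An [information_image()].
#' @param pulse An [influence_pulse()].
#' @param policy `"clamp_zero"` (default) or `"error"` for `E + D < 0`.
#' @return State value(s), bounded by `|A|`.
#' @export
#' @examples
#' ii <- information_image(E = 0.2, A = 1)
#' p <- influence_pulse(H = 0.5, T = 3, omega_d = 0.8)
#' perturbed_state(0.5, seq(0, 10, by = 0.5), ii, p)
perturbed_state <- function(x, t, image, pulse,
                            policy = c("clamp_zero", "error")) {
  policy <- match.arg(policy)
  stopifnot(inherits(image, "cogwell_image"), inherits(pulse, "cogwell_pulse"))
  n <- max(length(x), length(t))
  x <- rep_len(x, n)
  t <- rep_len(t, n)
  Eeff <- image$E + influence_at(pulse, t)
  if (any(Eeff < 0)) {
    if (policy == "error") {
      stop("negative effective energy: E + D < 0 at some t; use ",
           "policy = \"clamp_zero\" to clamp", call. = FALSE)
    }
    warning("E + D < 0 at ", sum(Eeff < 0),
            " time point(s); effective energy clamped to 0", call. = FALSE)
    Eeff[Eeff < 0] <- 0
  }
  k <- 2 * pi * sqrt(2 * image$m * Eeff) / image$h
  image$A * cos(k * x) * cos(4 * pi * image$E * t / image$h)
}
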