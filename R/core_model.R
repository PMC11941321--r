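#' Activity frequency of an information image
#'
#' The frequency of the oscillatory movements of an information image,
#' `omega_q = 2 pi m v1^2 / h = 4 pi E / h`, where `v1 = sqrt(2 E / m)` is the
#' kinetic speed inside the well. Zero if and only if `E = 0`.
#'
#' @param image An [information_image()].
#' @return Frequency in radians per unit time.
#' @export
#' @examples
#' omega_q(information_image(E = 1))  # 4 * pi
omega_q <- function(image) {
  stopifnot(inherits(image, "cogwell_image"))
  4 * pi * image$E / image$h
}

#' Kinetic speed inside the well
#'
#' `v1 = sqrt(2 E / m)`, from `E = m v1^2 / 2`.
#'
#' @inheritParams omega_q
#' @return Speed (dimensionless).
#' @export
kinetic_speed <- function(image) {
  stopifnot(inherits(image, "cogwell_image"))
  sqrt(2 * image$E / image$m)
}

#' Evanescent speed outside the well
#'
#' The magnitude of the imaginary velocity in Zone 2,
#' `|v2| = sqrt(2 (U0 - E) / m)`, from `m v2^2 / 2 = E - U0 = -(U0 - E)`.
#' Defined only for bound images (`E < U0`).
#'
#' @inheritParams omega_q
#' @param well A [potential_well()].
#' @return Speed (dimensionless).
#' @export
#' @examples
#' evanescent_speed(information_image(E = 0), potential_well(a = 1, U0 = 2))  # 2
evanescent_speed <- function(image, well) {
  stopifnot(inherits(image, "cogwell_image"), inherits(well, "cogwell_well"))
  check_bound(image, well)
  sqrt(2 * (well$U0 - image$E) / image$m)
}

# internal: spatial wavenumber inside the well, 2 pi sqrt(2 m E) / h
wavenumber_inside <- function(image) {
  2 * pi * sqrt(2 * image$m * image$E) / image$h
}

# internal: spatial decay constant outside the well, 2 pi sqrt(2 m (U0 - E)) / h
# (the dimensional analogue of the inside wavenumber with E -> U0 - E)
decay_outside <- function(image, well) {
  2 * pi * sqrt(2 * image$m * (well$U0 - image$E)) / image$h
}

#' State function inside the well (Zone 1)
#'
#' Self-oscillatory bound-state function at position `x` and time `t`:
#' `A f(2 pi sqrt(2 m E) x / h) cos(omega_q t + beta)` where `f` is `sin`
#' (the original standing-wave form) or `cos` (the form used for all
#' simulations), selected by `dialect`.
#'
#' @param x Position(s), strictly inside (-a/2, a/2).
#' @param t Time(s); recycled against `x`.
#' @param image An [information_image()].
#' @param well A [potential_well()].
#' @param dialect `"cosine"` (default) or `"sine"` spatial form.
#' @return State value(s).
#' @export
#' @examples
#' w <- potential_well(a = 2, U0 = 5)
#' ii <- information_image(E = 1)
#' phi_inside(0, 0, ii, w)             # cosine dialect: 1
#' phi_inside(0, 0, ii, w, "sine")     # 0
phi_inside <- function(x, t, image, well, dialect = c("cosine", "sine")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(image, "cogwell_image"), inherits(well, "cogwell_well"))
  check_bound(image, well)
  if (any(abs(x) >= well$a / 2)) {
    stop("zone error: x outside Zone 1 (-a/2, a/2); use phi_outside()",
         call. = FALSE)
  }
  k <- wavenumber_inside(image)
  sp <- if (dialect == "sine") sin(k * x) else cos(k * x)
  image$A * sp * cos(omega_q(image) * t + image$beta)
}

#' State function outside the well (Zone 2)
#'
#' Evanescent tail in Zone 2: the single surviving decaying exponential
#' (the growing one is discarded on each side) times the self-oscillatory
#' factor `cos(omega_q t + beta)`:
#' `coef * exp(-kappa |x|) * cos(omega_q t + beta)` with
#' `kappa = 2 pi sqrt(2 m (U0 - E)) / h`.
#'
#' In the internal-process regime the surviving coefficient is zero and the
#' state vanishes identically outside the well.
#'
#' @inheritParams phi_inside
#' @param coef Surviving exponential coefficient (C for the right side, B for
#'   the left); default 1. Set 0 for the internal regime.
#' @return State value(s); magnitude strictly decreasing in `|x|`.
#' @export
phi_outside <- function(x, t, image, well, coef = 1) {
  stopifnot(inherits(image, "cogwell_image"), inherits(well, "cogwell_well"))
  check_bound(image, well)
  if (any(abs(x) < well$a / 2)) {
    stop("zone error: x inside Zone 1; use phi_inside()", call. = FALSE)
  }
  kappa <- decay_outside(image, well)
  coef * exp(-kappa * abs(x)) * cos(omega_q(image) * t + image$beta)
}

#' Piecewise state function over both zones
#'
#' The composite state used in the simulations: a cosine-dialect interior
#' part for `|x| < a/2` plus an evanescent tail `C exp(-(4 pi E / h) |v2| |x|)`
#' outside, all multiplied by the common time factor `cos(4 pi E t / h)`.
#' The outside tail intentionally uses the activity-frequency-scaled decay
#' `(4 pi E / h) |v2|` of the composite form, not the Zone-2 bound-state decay
#' of [phi_outside()].
#'
#' The `"internal"` regime models processes within one mind: the outside
#' coefficient is forced to zero and the state vanishes beyond the walls.
#' The `"communication"` regime keeps `C`.
#'
#' @inheritParams phi_inside
#' @param regime `"internal"` (default; C forced to 0) or `"communication"`.
#' @param C Outside coefficient for the communication regime (default 1).
#' @return State value(s).
#' @export
phi_piecewise <- function(x, t, image, well,
                          regime = c("internal", "communication"), C = 1) {
  regime <- match.arg(regime)
  stopifnot(inherits(image, "cogwell_image"), inherits(well, "cogwell_well"))
  check_bound(image, well)
  if (regime == "internal") C <- 0
  n <- max(length(x), length(t))
  x <- rep_len(x, n)
  t <- rep_len(t, n)
  inside <- abs(x) < well$a / 2
  k <- wavenumber_inside(image)
  kappa <- omega_q(image) * evanescent_speed(image, well)
  sp <- numeric(n)
  sp[inside] <- image$A * cos(k * x[inside])
  sp[!inside] <- C * exp(-kappa * abs(x[!inside]))
  sp * cos(4 * pi * image$E * t / image$h)
}
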