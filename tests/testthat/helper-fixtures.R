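# Shared fixtures: a bound image in a standard well, and a
# parameter-recovery problem whose true parameters lie strictly inside the
# search bounds (and on the initial full-bounds grid of the adaptive
# search, so exact recovery is attainable at the grid resolution).

std_well <- function(a = 2, U0 = 5) potential_well(a = a, U0 = U0)

std_image <- function(E = 0.2, A = 1, beta = 0, omega0 = 1, h = 1, m = 1) {
  information_image(E = E, A = A, beta = beta, omega0 = omega0,
                    constants = model_constants(h = h, m = m))
}

std_pulse <- function(H = 0.5, T = 3, omega_d = 0.8, t0 = 0) {
  influence_pulse(H = H, T = T, omega_d = omega_d, t0 = t0)
}

recovery_bounds <- function() {
  list(E = c(0.01, 0.31), A = c(0.5, 3.5), H = c(0, 0.3),
       T = c(1, 7), omega_d = c(0.2, 2.6))
}

recovery_theta_star <- function() {
  c(E = 0.11, A = 2, H = 0.1, T = 4, omega_d = 1.0)
}

recovery_problem <- function(s = seq(0, 20, length.out = 40)) {
  model <- slice_model(std_image(E = 0.1, A = 1), std_pulse(), x_eval = 0.5)
  y <- model(recovery_theta_star(), s)
  fit_problem(data.frame(s = s, y = y), model,
              theta_names = c("E", "A", "H", "T", "omega_d"),
              bounds = recovery_bounds())
}

# a small linear toy problem for optimizer oracle checks
toy_problem <- function() {
  model <- function(theta, s) theta[["b0"]] + theta[["b1"]] * s
  s <- 1:5
  y <- 0.7 + 0.33 * s
  fit_problem(data.frame(s = s, y = y), model, c("b0", "b1"),
              list(b0 = c(-2, 2), b1 = c(-1, 1)))
}
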