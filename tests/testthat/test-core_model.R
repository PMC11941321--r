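test_that("activity frequency follows 4*pi*E/h", {
  expect_equal(omega_q(std_image(E = 1)), 4 * pi)
  expect_equal(omega_q(std_image(E = 0)), 0)
  # ratio invariance: doubling E and h together leaves omega_q unchanged
  expect_equal(omega_q(std_image(E = 2, h = 2)), 4 * pi)
  expect_error(model_constants(h = 0), "h")
})

test_that("evanescent speed is sqrt(2(U0 - E)/m) and needs a bound image", {
  expect_equal(evanescent_speed(std_image(E = 0), std_well(U0 = 2)), 2)
  expect_equal(evanescent_speed(std_image(E = 1, m = 2), std_well(U0 = 3)),
               sqrt(2))
  eps <- 1e-12
  expect_lt(evanescent_speed(std_image(E = 2 - eps), std_well(U0 = 2)), 2e-6)
  expect_error(evanescent_speed(std_image(E = 5), std_well(U0 = 5)), "unbound")
  expect_error(evanescent_speed(std_image(E = 9), std_well(U0 = 5)), "unbound")
})

test_that("inside state function matches the closed form in both dialects", {
  w <- std_well()
  ii <- std_image(E = 1, A = 1)
  expect_equal(phi_inside(0, 0.37, ii, w, "sine"), 0)
  expect_equal(phi_inside(0, 0, ii, w, "cosine"), 1)
  # temporal zero of the self-oscillatory factor: 4*pi*E*t/h = pi/2
  tq <- (pi / 2) / (4 * pi)
  expect_equal(phi_inside(0, tq, ii, w, "cosine"), 0, tolerance = 1e-15)
  # direct evaluation against the formula at an arbitrary point
  x <- 0.31; t <- 1.7
  k <- 2 * pi * sqrt(2 * 1 * 1) / 1
  expect_equal(phi_inside(x, t, ii, w, "sine"),
               sin(k * x) * cos(4 * pi * t))
  expect_error(phi_inside(1.2, 0, ii, w), "zone")
})

test_that("outside state function decays monotonically and vanishes with C = 0", {
  w <- std_well()
  ii <- std_image(E = 0.5)
  expect_lt(abs(phi_outside(50, 0.2, ii, w)), 1e-200)
  expect_gt(abs(phi_outside(w$a / 2, 0.1, ii, w)),
            abs(phi_outside(w$a, 0.1, ii, w)))
  expect_equal(phi_outside(c(1, 1.5, 3), 0.4, ii, w, coef = 0),
               c(0, 0, 0))
  # symmetric: left tail mirrors the right tail
  expect_equal(phi_outside(-1.3, 0.4, ii, w), phi_outside(1.3, 0.4, ii, w))
  expect_error(phi_outside(0.2, 0, ii, w), "zone")
})

test_that("spatial parts satisfy their second-order ODEs by central differences", {
  w <- std_well()
  ii <- std_image(E = 0.7, A = 1.3)
  # Zone 1: phi'' + (8 pi^2 m E / h^2) phi = 0
  x <- seq(-0.95, 0.95, length.out = 10000)
  h <- x[2] - x[1]
  phi <- phi_inside(x, 0, ii, w)
  i <- 2:(length(x) - 1)
  d2 <- (phi[i + 1] - 2 * phi[i] + phi[i - 1]) / h^2
  k2 <- 8 * pi^2 * 1 * 0.7 / 1
  expect_lt(max(abs(d2 + k2 * phi[i])) / max(abs(k2 * phi)), 1e-6)
  # Zone 2: phi'' - kappa^2 phi = 0
  x2 <- seq(1, 2, length.out = 10000)
  h2 <- x2[2] - x2[1]
  phi2 <- phi_outside(x2, 0, ii, w)
  j <- 2:(length(x2) - 1)
  d2o <- (phi2[j + 1] - 2 * phi2[j] + phi2[j - 1]) / h2^2
  kap2 <- (2 * pi * sqrt(2 * (5 - 0.7)))^2
  expect_lt(max(abs(d2o - kap2 * phi2[j])) / max(abs(kap2 * phi2)), 1e-6)
})

test_that("state functions are periodic in time with period 2*pi/omega_q", {
  w <- std_well()
  ii <- std_image(E = 0.4, A = 2, beta = 0.3)
  period <- 2 * pi / omega_q(ii)
  x <- seq(-0.9, 0.9, length.out = 21)
  t <- seq(0, 5, length.out = 11)
  for (tt in t) {
    expect_equal(phi_inside(x, tt + period, ii, w),
                 phi_inside(x, tt, ii, w), tolerance = 1e-12)
  }
  expect_equal(phi_outside(1.4, t + period, ii, w),
               phi_outside(1.4, t, ii, w), tolerance = 1e-12)
})

test_that("piecewise state vanishes outside the well in the internal regime", {
  w <- std_well()
  ii <- std_image(E = 0.5, A = 1.5)
  xout <- c(-3, -1.2, 1, 1.7, 4)
  expect_equal(phi_piecewise(xout, 0.3, ii, w, "internal"), rep(0, 5))
  # communication regime with C = 0 is identical to internal everywhere
  xall <- seq(-2, 2, length.out = 41)
  expect_equal(phi_piecewise(xall, 0.9, ii, w, "communication", C = 0),
               phi_piecewise(xall, 0.9, ii, w, "internal"))
  expect_equal(phi_piecewise(0, 0, std_image(E = 0.5, A = 1), w), 1)
})
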