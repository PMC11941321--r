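test_that("zone-1 force vanishes where both terms vanish", {
  w <- std_well()
  cfg_off <- integrator_config(dt = 0.01, t_end = 1, delta_on = FALSE)
  ii <- std_image(E = 0.2, A = 1, omega0 = 2)
  expect_equal(force_zone1(0, c(0, 0.5, 3), ii, w, cfg_off), c(0, 0, 0))
  cfg_on <- integrator_config(dt = 0.01, t_end = 1, delta_on = TRUE)
  ii0 <- std_image(E = 0.2, A = 0)
  sigma <- w$a / 100
  xfar <- seq(-0.5, 0.5, length.out = 11)  # > 10 sigma from the right wall
  expect_true(all(abs(force_zone1(xfar, 0.3, ii0, w, cfg_on)) < 1e-12))
})

test_that("the regularized barrier impulse integrates to U0 across the wall", {
  w <- std_well(a = 2, U0 = 5)
  cfg <- integrator_config(dt = 0.01, t_end = 1, delta_on = TRUE)
  ii0 <- std_image(E = 0.2, A = 0)
  q <- stats::integrate(function(x) force_zone1(x, 0, ii0, w, cfg),
                        lower = w$a / 2 - 0.5, upper = w$a / 2 + 0.5,
                        rel.tol = 1e-10)
  expect_equal(q$value, w$U0, tolerance = 1e-6)
  # mirrored impulse doubles the total when enabled
  cfgm <- integrator_config(dt = 0.01, t_end = 1, delta_on = TRUE,
                            mirror_delta = TRUE)
  qm <- stats::integrate(function(x) force_zone1(x, 0, ii0, w, cfgm),
                         lower = -w$a, upper = w$a, rel.tol = 1e-10)
  expect_equal(qm$value, 2 * w$U0, tolerance = 1e-6)
})

test_that("zone-2 force decays away from the well with the side's coefficient", {
  w <- std_well()
  ii <- std_image(E = 0.5)
  expect_equal(force_zone2(1.5, 0.3, ii, w, "right", coef = 0), 0)
  expect_lt(abs(force_zone2(60, 0, ii, w, "right")), 1e-200)
  expect_gt(abs(force_zone2(w$a / 2, 0.1, ii, w, "right")),
            abs(force_zone2(w$a, 0.1, ii, w, "right")))
  expect_gt(abs(force_zone2(-w$a / 2, 0.1, ii, w, "left")),
            abs(force_zone2(-w$a, 0.1, ii, w, "left")))
})

test_that("force-free motion is uniform", {
  w <- std_well()
  ii <- std_image(E = 0, A = 0)
  tr <- simulate_motion(ii, w, x0 = 0, v0 = 1,
                        integrator_config(dt = 0.01, t_end = 2,
                                          delta_on = FALSE))
  expect_equal(tail(tr$x, 1), 2, tolerance = 1e-12)
  expect_equal(tail(tr$v, 1), 1, tolerance = 1e-12)
})

test_that("static forcing conserves m v^2/2 + A cos(omega0 x)", {
  # omega_q = 0 (E = 0), beta = 0, delta off: F = A omega0 sin(omega0 x)
  # derives from the potential V = A cos(omega0 x)
  w <- std_well(a = 4, U0 = 5)
  ii <- std_image(E = 0, A = 1, omega0 = pi)
  tr <- simulate_motion(ii, w, x0 = 0.8, v0 = 0.3,
                        integrator_config(dt = 1e-3, t_end = 10,
                                          delta_on = FALSE))
  expect_true(all(tr$zone == 1L))
  En <- tr$v^2 / 2 + cos(pi * tr$x)
  expect_lt(max(abs(En - En[1])) / abs(En[1]), 1e-6)
  # cross-check the end state against a 10x finer reference run
  ref <- simulate_motion(ii, w, x0 = 0.8, v0 = 0.3,
                         integrator_config(dt = 1e-4, t_end = 10,
                                           delta_on = FALSE))
  expect_equal(tail(tr$x, 1), tail(ref$x, 1), tolerance = 1e-8)
})

test_that("the integrator shows 4th-order step-size convergence", {
  w <- std_well(a = 4, U0 = 5)
  ii <- std_image(E = 0, A = 1, omega0 = pi)
  xend <- vapply(c(0.004, 0.002, 0.001), function(dt) {
    tail(simulate_motion(ii, w, 0.8, 0.3,
                         integrator_config(dt = dt, t_end = 5,
                                           delta_on = FALSE))$x, 1)
  }, numeric(1))
  d1 <- abs(xend[2] - xend[1])
  d2 <- abs(xend[3] - xend[2])
  expect_lt(d2, d1 / 8)  # ~1/16 for an exact 4th-order scheme
})

test_that("the fast integrator acceleration equals the public force dispatch", {
  w <- std_well()
  ii <- information_image(E = 0.3, A = 1.2, beta = 0.4, omega0 = 2,
                          constants = model_constants(m = 1.5))
  cfg <- integrator_config(dt = 0.01, t_end = 1, delta_width = 0.05,
                           delta_on = TRUE, mirror_delta = TRUE,
                           B = 0.3, C = 0.7)
  acc <- cogwell:::make_accel(ii, w, cfg)
  for (x in c(-1.8, -1.0, -0.6, 0, 0.4, 0.97, 1.0, 1.3, 2.5)) {
    for (t in c(0, 0.7, 2.1)) {
      expect_equal(acc(x, t), cogwell:::dispatch_accel(x, t, ii, w, cfg),
                   tolerance = 1e-14)
    }
  }
})

test_that("trajectories are bit-identical for identical configurations", {
  w <- std_well()
  ii <- std_image(E = 0.3, A = 0.8, omega0 = 2)
  cfg <- integrator_config(dt = 0.001, t_end = 1, delta_width = 0.05)
  t1 <- simulate_motion(ii, w, 0.2, 0.4, cfg)
  t2 <- simulate_motion(ii, w, 0.2, 0.4, cfg)
  expect_identical(t1$x, t2$x)
  expect_identical(t1$v, t2$v)
})

test_that("exit detection requires threshold kinetic energy near a wall", {
  w <- std_well(a = 2, U0 = 5)
  ii <- std_image(E = 0, A = 0)
  # slow image: never exceeds the barrier
  tr_slow <- simulate_motion(ii, w, 0, 0.5,
                             integrator_config(dt = 0.01, t_end = 2,
                                               delta_on = FALSE))
  expect_identical(nrow(detect_exit(tr_slow)), 0L)
  # fast image starting one regularization width inside the wall, forces off:
  # exactly the first sample is both near the wall and above threshold
  vp <- threshold_velocity(w)
  expect_equal(vp, sqrt(2 * 5))
  sigma <- w$a / 100
  tr_fast <- simulate_motion(ii, w, w$a / 2 - sigma / 2, 1.1 * vp,
                             integrator_config(dt = 0.05, t_end = 1,
                                               delta_on = FALSE))
  ev <- detect_exit(tr_fast)
  # brute-force scan oracle over the recorded samples
  ke <- tr_fast$v^2 / 2
  near <- abs(abs(tr_fast$x) - w$a / 2) <= sigma
  expect_equal(ev$time, tr_fast$times[near & ke >= w$U0])
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$time, 0)
  # an effectively infinite barrier admits no exits
  w_inf <- std_well(a = 2, U0 = 1e12)
  tr3 <- simulate_motion(ii, w_inf, 0, 3,
                         integrator_config(dt = 0.01, t_end = 1,
                                           delta_on = FALSE))
  expect_identical(nrow(detect_exit(tr3)), 0L)
})

test_that("under-resolved barrier crossings raise a warning", {
  w <- std_well()
  ii <- std_image(E = 0, A = 0)
  expect_warning(
    simulate_motion(ii, w, 0.9, 3.5,
                    integrator_config(dt = 0.05, t_end = 0.5,
                                      delta_on = TRUE)),
    "under-resolved")
})

test_that("trajectory export has the documented columns", {
  w <- std_well()
  ii <- std_image(E = 0.2, A = 0.5, omega0 = 2)
  tr <- simulate_motion(ii, w, 0, 0.3,
                        integrator_config(dt = 0.01, t_end = 1))
  f <- tempfile(fileext = ".csv")
  write_trajectory(tr, f)
  df <- utils::read.csv(f)
  expect_named(df, c("time", "x", "v", "zone", "exit_flag"))
  expect_equal(nrow(df), length(tr$times))
})
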