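test_that("the SSE objective behaves like a sum of squared residuals", {
  pr <- toy_problem()
  expect_equal(fit_objective(c(0.7, 0.33), pr), 0)  # perfect fit
  # constant-model residuals: model (1, 2), observed (0, 0) -> 1^2 + 2^2
  pr2 <- fit_problem(data.frame(s = 1:2, y = c(0, 0)),
                     function(theta, s) c(1, 2) * theta[["a"]],
                     "a", list(a = c(0.1, 3)))
  expect_equal(fit_objective(1, pr2), 5)
  # doubling all residuals quadruples the objective
  expect_equal(fit_objective(2, pr2), 20)
  expect_error(fit_objective(5, pr2), "bounds")
})

test_that("an explicit scale parameter multiplies the model curve", {
  model <- function(theta, s) theta[["A"]] * cos(s)
  s <- seq(0, 3, 0.5)
  y <- 3 * cos(s)
  pr <- fit_problem(data.frame(s, y), model, c("A", "scale"),
                    list(A = c(0.1, 5), scale = c(0.1, 5)))
  # (A, scale) enter multiplicatively: (3, 1) and (1.5, 2) are equivalent
  expect_equal(fit_objective(c(3, 1), pr), 0)
  expect_equal(fit_objective(c(1.5, 2), pr), 0)
  expect_error(fit_problem(data.frame(s, y), model, c("A", "scale"),
                           list(A = c(0.1, 5), scale = c(-1, 5))),
               "scale")
})

test_that("local descent never worsens the starting objective", {
  pr <- toy_problem()
  # starting at the optimum of a noiseless self-generated target: stays at 0
  ft0 <- fit_local(pr, c(0.7, 0.33))
  expect_equal(ft0$objective, 0)
  ft <- fit_local(pr, c(1.5, -0.5))
  expect_lte(ft$objective, fit_objective(c(1.5, -0.5), pr))
  expect_lt(ft$objective, 1e-6)
  expect_equal(unname(ft$theta_hat), c(0.7, 0.33), tolerance = 1e-3)
  # running minimum of the trace is non-increasing by construction
  expect_equal(ft$objective, min(ft$trace$objective))
  expect_true(all(diff(cummin(ft$trace$objective)) <= 0))
  # deterministic given init
  ft2 <- fit_local(pr, c(1.5, -0.5))
  expect_identical(ft$theta_hat, ft2$theta_hat)
})

test_that("a single-parameter fit recovers the least-squares mean", {
  # m(s; theta) = theta: the optimum is the sample mean of y
  y <- c(1.2, 3.4, 2.2, 2.9)
  pr <- fit_problem(data.frame(s = 1:4, y = y),
                    function(theta, s) rep(theta[["mu"]], length(s)),
                    "mu", list(mu = c(0, 5)))
  ft <- fit_local(pr, 1)
  expect_equal(unname(ft$theta_hat), mean(y), tolerance = 1e-6)
})

test_that("grid search with refinements disabled equals exhaustive enumeration", {
  pr <- toy_problem()
  cfgs <- grid_config(n_points_per_axis = 7, n_refinements = 0, n_starts = 1,
                      seed = 3)
  ft <- fit_grid_adaptive(pr, cfgs)
  # independent oracle: enumerate the identical 7 x 7 grid
  g1 <- seq(-2, 2, length.out = 7)
  g2 <- seq(-1, 1, length.out = 7)
  grid <- expand.grid(b0 = g1, b1 = g2, KEEP.OUT.ATTRS = FALSE)
  objs <- apply(grid, 1, function(th) sum((th[1] + th[2] * (1:5) -
                                             pr$y)^2))
  b <- which.min(objs)
  expect_equal(unname(ft$theta_hat), unname(unlist(grid[b, ])))
  expect_equal(ft$objective, objs[[b]])
  expect_identical(ft$n_evals, 49L)
})

test_that("refinement cannot worsen the best objective", {
  pr <- recovery_problem()
  ft <- fit_grid_adaptive(pr, grid_config(n_refinements = 3, n_starts = 1,
                                          seed = 1))
  # per-grid bests of the single (unclipped, centred) start are
  # non-increasing: each shrunk box keeps the previous best as a grid point
  expect_true(all(diff(ft$trace$objective) <= 1e-12))
})

test_that("identical seeds give identical fits; omega_d sign is unidentifiable", {
  pr <- recovery_problem(s = seq(0, 10, length.out = 15))
  cfgs <- grid_config(n_refinements = 2, n_starts = 3, seed = 42)
  f1 <- fit_grid_adaptive(pr, cfgs)
  f2 <- fit_grid_adaptive(pr, cfgs)
  expect_identical(f1$theta_hat, f2$theta_hat)
  expect_identical(f1$objective, f2$objective)
  expect_identical(f1$trace, f2$trace)
  # cos is even in omega_d: mirrored frequencies give identical curves
  model <- slice_model(std_image(E = 0.1, A = 1), std_pulse(), x_eval = 0.5)
  th <- recovery_theta_star()
  thm <- th; thm[["omega_d"]] <- -th[["omega_d"]]
  s <- seq(0, 20, length.out = 50)
  expect_equal(model(th, s), model(thm, s))
})

test_that("a noiseless interior target is recovered to the final grid resolution", {
  pr <- recovery_problem()
  cfgs <- grid_config(seed = 7)
  ft <- fit_grid_adaptive(pr, cfgs)
  expect_lt(ft$objective, 1e-8)
  err <- abs(ft$theta_hat - recovery_theta_star())
  expect_true(all(err <= final_grid_spacing(pr, cfgs)))
})
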