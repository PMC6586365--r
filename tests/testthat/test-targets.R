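test_that("step targets implement the periodic fixation protocol", {
  tr <- make_step_targets(2, duration = 2.5, dt = 1e-3, period = 0.5,
                          fix_len = 0.1, seed = 1)
  expect_equal(traj_dims(tr), 2)
  # 5 fixation windows of 100 ms each
  starts <- sum(diff(c(FALSE, tr$fixed)) == 1)
  expect_equal(starts, 5)
  expect_equal(sum(tr$fixed) * 1e-3, 0.5, tolerance = 1e-6)
  # held value persists between fixations (piecewise constant per period)
  x <- traj_matrix(tr)
  per <- floor(tr$time / 0.5)
  for (p in unique(per))
    expect_equal(max(apply(x[, per == p, drop = FALSE], 1, stats::sd)), 0)
  # degenerate clamp: fixation the whole period
  tr2 <- make_step_targets(2, 1, 1e-3, period = 0.5, fix_len = 0.5, seed = 1)
  expect_true(all(tr2$fixed))
  # seeded determinism
  expect_identical(make_step_targets(3, 2, 1e-3, seed = 42),
                   make_step_targets(3, 2, 1e-3, seed = 42))
  expect_error(make_step_targets(2, 2.4, 1e-3, period = 0.5, seed = 1),
               "multiple")
  expect_error(make_step_targets(2, -1, 1e-3, seed = 1))
})

test_that("oscillator targets satisfy their defining linear ODE", {
  dt <- 1e-3
  tr <- make_oscillator_targets(2, duration = 1, dt = dt, amplitude = 1)
  x <- traj_matrix(tr)
  # exactly 2 full cycles: endpoints return to start
  expect_equal(unname(x[, 1]), c(1, 0), tolerance = 1e-9)
  expect_equal(unname(x[, ncol(x)]),
               c(cos(2 * pi * 2 * (1 - dt)), sin(2 * pi * 2 * (1 - dt))),
               tolerance = 1e-9)
  # finite-difference residual against dx/dt = A x
  A <- oscillator_A(2)
  xdot <- (x[, -1] - x[, -ncol(x)]) / dt
  mid <- (x[, -1] + x[, -ncol(x)]) / 2
  resid <- sqrt(colSums((xdot - A %*% mid)^2))
  expect_lt(max(resid), 10 * dt * 1 * (2 * pi * 2)^2)
  # f = 0 gives a constant trajectory
  tr0 <- make_oscillator_targets(0, 0.5, 1e-3)
  expect_equal(max(abs(traj_matrix(tr0) - c(1, 0))), 0)
})

test_that("encoder draws follow their schemes", {
  K <- draw_encoders("unit_sphere_rows", 500, 3, seed = 2)
  expect_equal(sqrt(rowSums(unclass(K)^2)), rep(1, 500), tolerance = 1e-12)
  Kb <- draw_encoders("uniform_box", 2000, 2, scale = 100, seed = 3)
  expect_true(all(abs(Kb) <= 100))
  # column covariance of the uniform box: diagonal ~ scale^2 / 3
  cv <- stats::cov(unclass(Kb))
  se <- 100^2 / 3 * sqrt(2 / 2000) * 3      # ~3 sd of a variance estimate
  expect_lt(max(abs(diag(cv) - 100^2 / 3)), se)
  expect_identical(draw_encoders("uniform_box", 10, 2, seed = 1),
                   draw_encoders("uniform_box", 10, 2, seed = 1))
  expect_error(draw_encoders("nope", 10, 2, seed = 1))
  expect_error(draw_encoders("uniform_box", 2, 5, seed = 1))
})

test_that("limit-cycle reference integrates the 4-D oscillator field", {
  # on-cycle start stays on the cycle
  tr <- limit_cycle_reference(x0 = c(1, 0, 1, 0), duration = 2, dt = 1e-3)
  x <- traj_matrix(tr)
  r1 <- sqrt(colSums(x[1:2, ]^2)); r2 <- sqrt(colSums(x[3:4, ]^2))
  expect_lt(max(abs(c(r1, r2) - 1)), 1e-3)
  # fixed point at the origin
  tr0 <- limit_cycle_reference(x0 = rep(0, 4), duration = 0.5, dt = 1e-3)
  expect_equal(max(abs(traj_matrix(tr0))), 0)
  # convergence from r = 0.5: the radial ODE dr/dt = a r (1 - r^2) reaches
  # 0.99 when t = log(r^2 (1-r0^2) / (r0^2 (1-r^2))) / (2a); integrate past it
  a <- 0.2; r0 <- 0.5; rT <- 0.99
  t_conv <- log(rT^2 * (1 - r0^2) / (r0^2 * (1 - rT^2))) / (2 * a)
  tr3 <- limit_cycle_reference(alpha = a, x0 = c(0.5, 0, 0.5, 0),
                               duration = t_conv + 1, dt = 1e-3)
  xe <- traj_matrix(tr3)[, ncol(traj_matrix(tr3))]
  expect_lt(abs(sqrt(sum(xe[1:2]^2)) - 1), 0.01)
  expect_lt(abs(sqrt(sum(xe[3:4]^2)) - 1), 0.01)
})

test_that("oscillator field is tangential on the cycle with radial decay -2a", {
  expect_equal(oscillator_field(rep(0, 4)), rep(0, 4))
  x <- c(1, 0, 0, 1)
  f <- oscillator_field(x, omega = 2 * pi * 2, alpha = 0.2)
  expect_equal(sum(f[1:2] * x[1:2]), 0, tolerance = 1e-12)
  expect_equal(sum(f[3:4] * x[3:4]), 0, tolerance = 1e-12)
  # radial eigenvalue at r = 1: d/dr [a r (1 - r^2)] = -2 a
  a <- 0.2; h <- 1e-6
  dr <- (a * (1 + h) * (1 - (1 + h)^2) - a * (1 - h) * (1 - (1 - h)^2)) / (2 * h)
  expect_equal(dr, -2 * a, tolerance = 1e-6)
})

test_that("trajectories serialize to delimited text and back", {
  tr <- make_step_targets(2, 1, 1e-2, seed = 9)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory(tr, path)
  back <- read_trajectory(path)
  expect_equal(traj_matrix(back), traj_matrix(tr), tolerance = 1e-12)
  expect_equal(back$fixed, tr$fixed)
})
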