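test_that("gain/bias calibration hits the two defining rate conditions", {
  tn <- calibrate_gain_bias(200, seed = 1)
  expect_true(all(tn$max_rates >= 80 & tn$max_rates <= 120))
  expect_true(all(tn$intercepts >= -1 & tn$intercepts < 1))
  # rate 0 at the intercept along the preferred direction (floating-point
  # cancellation at intercepts ~ 1 can leave a few Hz)
  r_ic <- lif_rate(tn$gains * tn$intercepts + tn$biases, tn$params)
  expect_equal(stats::median(r_ic), 0)
  expect_lt(max(r_ic), 5)
  # rate = drawn max rate at x = 1 along the preferred direction
  r_max <- lif_rate(tn$gains + tn$biases, tn$params)
  expect_equal(r_max, tn$max_rates, tolerance = 0.5 / 80)
  # refractory ceiling check
  expect_error(calibrate_gain_bias(5, max_rates = c(499, 501),
                                   params = lif_params(t_ref = 0.002)),
               "refractory")
})

test_that("evaluation points fill the latent box uniformly", {
  ev <- sample_evaluation_points(2, 2000, seed = 2)
  expect_equal(dim(ev), c(2000, 2))
  expect_true(all(ev >= -1 & ev <= 1))
  # per-dimension means near 0 (3 SEs of uniform on [-1,1])
  expect_lt(max(abs(colMeans(ev))), 3 * sqrt(1 / 3 / 2000))
  expect_identical(sample_evaluation_points(3, 50, seed = 7),
                   sample_evaluation_points(3, 50, seed = 7))
})

test_that("estimated activities match brute-force simulated traces", {
  net <- tiny_nef(n = 40, n_eval = 300, seed = 3)
  ev <- sample_evaluation_points(2, 5, seed = 9)
  act <- estimate_activities(net$tuning, net$K, ev)
  expect_true(all(act >= 0))
  # simulate each evaluation point and compare filtered-trace means (in Hz)
  p <- net$tuning$params
  for (m in 1:5) {
    J <- net$tuning$gains * as.numeric(unclass(net$K) %*% ev[m, ]) +
      net$tuning$biases
    sim <- simulate_lif(matrix(J, 40, 4000), p, 4, 1e-3, tau_syn = 0.01)
    emp <- tabulate(sim$raster$neuron, 40) / 4
    active <- act[m, ] > 20
    expect_lt(max(abs(emp[active] - act[m, active]) / act[m, active]), 0.1)
  }
})

test_that("decoder solve equals the ridge normal equations", {
  set.seed(4)
  A <- matrix(rexp(5 * 3), 5, 3)
  y <- matrix(rnorm(10), 5, 2)
  ridge <- 0.05
  D <- solve_decoders(A, y, ridge)
  lam <- (ridge * max(A))^2 * 5
  D_ref <- t(solve(crossprod(A) + lam * diag(3), crossprod(A, y)))
  expect_equal(D, D_ref, tolerance = 1e-10)
  # zero targets give zero decoders
  expect_equal(max(abs(solve_decoders(A, matrix(0, 5, 2), 0.01))), 0)
  # scalar regression recovers the proportionality constant
  a1 <- matrix(seq(1, 5), 5, 1)
  d1 <- solve_decoders(a1, 0.3 * a1[, 1], ridge = 0)
  expect_equal(as.numeric(d1), 0.3, tolerance = 1e-10)
  # rank-deficient activities without ridge fail loudly
  A2 <- cbind(a1, a1)
  expect_error(solve_decoders(A2, rnorm(5), ridge = 0), "rank")
})

test_that("dynamics transform embeds the latent dynamics in the decoders", {
  Phi <- matrix(rnorm(2 * 30), 2, 30)
  expect_equal(dynamics_transform(matrix(0, 2, 2), Phi, 0.01), Phi)
  expect_equal(dynamics_transform(diag(2) / 0.01, Phi, 0.01), 2 * Phi)
  # oscillator at 2 Hz, tau = 10 ms: relative change = ||tau A||_2 = 2pi f tau
  A <- oscillator_A(2)
  G <- dynamics_transform(A, Phi, 0.01)
  rel <- norm(G - Phi, "2") / norm(Phi, "2")
  expect_equal(norm(0.01 * A, "2"), 2 * pi * 2 * 0.01, tolerance = 1e-12)
  expect_lte(rel, norm(0.01 * A, "2") + 1e-12)
})

test_that("assembled weights are the rank-D product with folded gains", {
  net <- tiny_nef(n = 50, seed = 6)
  W <- assemble_weights(net$K, net$Phi, net$tuning$gains)
  expect_equal(dim(W), c(50, 50))
  expect_lte(qr(W)$rank, 2)
  u <- rnorm(50)
  expect_equal(as.numeric(W %*% u),
               as.numeric(net$tuning$gains *
                            (unclass(net$K) %*% (net$Phi %*% u))),
               tolerance = 1e-12)
  # D = 1 all-ones check
  W1 <- assemble_weights(matrix(1, 4, 1), matrix(1, 1, 4), rep(2, 4))
  expect_equal(W1, matrix(2, 4, 4))
})

test_that("closed-loop NEF retains clamped values between fixations", {
  net <- build_nef_network(500, 2, 1500, seed = 8)
  tr <- make_step_targets(2, 2.5, 1e-3, seed = 18)
  sim <- simulate_nef(net, tr, seed = 28)
  X <- traj_matrix(sim$x_dec); Xt <- traj_matrix(tr)
  free <- !tr$fixed
  drift <- sqrt(mean((X[, free] - Xt[, free])^2))
  # integrators drift between fixations (decode-error vector field); the
  # drift must stay below the typical inter-target spacing (~0.94)
  expect_lt(drift, 0.7)
})
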