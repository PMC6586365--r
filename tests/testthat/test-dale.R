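test_that("constraint masks enforce sparsity and Dale's law", {
  C <- make_constraint_mask(5000, xi = 0.75, eps_frac = 0.8, seed = 1)
  m <- unclass(C)
  # ~25% of entries allowed (binomial CI)
  p_nz <- mean(m != 0)
  expect_lt(abs(p_nz - 0.25), 3 * sqrt(0.25 * 0.75 / length(m)) + 1e-4)
  # column-consistent signs: excitatory first 80% of presynaptic columns
  n_exc <- attr(C, "n_exc")
  expect_equal(n_exc, 4000)
  expect_true(all(m[, 1:n_exc] %in% c(0L, 1L)))
  expect_true(all(m[, (n_exc + 1):5000] %in% c(0L, -1L)))
  # degenerate all-masked case
  expect_true(all(unclass(make_constraint_mask(50, xi = 1, seed = 2)) == 0))
})

test_that("gram-based NNLS matches pracma and brute-force active sets", {
  skip_if_not_installed("pracma")
  set.seed(3)
  for (rep in 1:20) {
    m <- 30; p <- 5
    A <- matrix(rnorm(m * p), m, p)
    b <- rnorm(m)
    x <- neuromodes:::cpp_nnls_gram(crossprod(A), crossprod(A, b), 200L)
    x_or <- pracma::lsqnonneg(A, b)$x
    expect_equal(as.numeric(x), as.numeric(x_or), tolerance = 1e-8)
    x_bf <- brute_nnls(A, b)
    expect_lt(sum((b - A %*% x)^2), sum((b - A %*% x_bf)^2) + 1e-8)
    expect_equal(as.numeric(x), x_bf, tolerance = 1e-6)
  }
})

test_that("constrained row solves honor every sign constraint", {
  set.seed(4)
  n <- 30; d <- 2; m <- 200
  K <- unclass(draw_encoders("unit_sphere_rows", n, d, seed = 5))
  tn <- calibrate_gain_bias(n, seed = 6)
  ev <- sample_evaluation_points(d, m, seed = 7)
  C <- make_constraint_mask(n, xi = 0.5, eps_frac = 0.7, seed = 8)
  cw <- solve_constrained_weights(K, tn, NULL, ev, C, tau_syn = 0.01)
  W <- cw$W
  expect_true(all(W[unclass(C) == 0] == 0))
  expect_true(all(W[unclass(C) == 1] >= 0))
  expect_true(all(W[unclass(C) == -1] <= 0))
  expect_true(all(cw$converged))
  # a 3-neuron row with a sign conflict matches exhaustive search
  A3 <- estimate_activities(tn, K, ev)[, 1:3]
  y <- A3 %*% c(1, -0.5, 0.3) + rnorm(m, sd = 1)
  signs <- c(1, 1, -1)
  x_solver <- neuromodes:::cpp_nnls_gram(
    crossprod(A3 %*% diag(signs)), crossprod(A3 %*% diag(signs), y), 200L)
  x_bf <- brute_nnls(A3 %*% diag(signs), y)
  expect_equal(as.numeric(x_solver), x_bf, tolerance = 1e-6)
})

test_that("unconstrained-compatible targets reduce to plain least squares", {
  set.seed(9)
  m <- 100; p <- 4
  A <- matrix(rexp(m * p), m, p)
  coef <- c(0.5, 1, 0.2, 2)
  b <- A %*% coef
  x <- neuromodes:::cpp_nnls_gram(crossprod(A), crossprod(A, b), 200L)
  expect_equal(as.numeric(x), coef, tolerance = 1e-8)
})

test_that("weight statistics summarize a Daleian matrix", {
  set.seed(10)
  W <- matrix(0, 40, 40)
  W[, 1:32] <- abs(rnorm(40 * 32)) * (runif(40 * 32) < 0.3)
  W[, 33:40] <- -abs(rnorm(40 * 8)) * (runif(40 * 8) < 0.6)
  st <- weight_statistics(W, eps_frac = 0.8)
  expect_equal(st$p_conn_exc, mean(W[, 1:32] != 0), tolerance = 1e-12)
  expect_equal(st$p_conn_inh, mean(W[, 33:40] != 0), tolerance = 1e-12)
  expect_equal(st$numerical_rank, qr(W)$rank)
  g <- glance(st)
  expect_equal(g$log_weight_kurtosis - 3, g$log_weight_kurtosis_excess)
  # all-zero matrix: probabilities 0
  st0 <- weight_statistics(matrix(0, 10, 10), eps_frac = 0.5)
  expect_equal(st0$p_conn_exc, 0)
  expect_equal(st0$p_conn_inh, 0)
})

test_that("desk-scale Daleian solve is Dale-compliant with rank above D", {
  net <- build_dale_network(n = 120, d = 4, n_eval = 1500, seed = 11)
  W <- net$W; C <- unclass(net$mask)
  expect_true(all(W[C == 0] == 0))
  expect_true(all(sign(W[C != 0]) %in% c(0, C[C != 0])))
  st <- weight_statistics(W)
  expect_gt(st$numerical_rank, 4)
  expect_gt(st$ei_balance_cor, 0.8)
})
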