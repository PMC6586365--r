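test_that("inside perturbation matrices have the stated forms", {
  Q <- make_inside_Q("rot45", 2)
  expect_equal(Q %*% t(Q), diag(2), tolerance = 1e-14)
  expect_equal(Q, matrix(c(cos(pi / 4), sin(pi / 4),
                           -sin(pi / 4), cos(pi / 4)), 2, 2))
  expect_equal(make_inside_Q("permutation", 2), matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(qr(make_inside_Q("same_element", 3, seed = 1))$rank, 1)
  Qg <- make_inside_Q("gaussian", 4, seed = 2)
  expect_equal(dim(Qg), c(4, 4))
  expect_error(make_inside_Q("rot45", 3))
  # explicit permutation
  Qp <- make_inside_Q("permutation", 4, perm = c(3, 4, 1, 2))
  x <- 1:4
  expect_equal(as.numeric(x %*% Qp), x[c(3, 4, 1, 2)])
})

test_that("outside perturbations are genuine row permutations", {
  Q <- make_outside_Q("block_swap", 10)
  expect_equal(Q %*% Q, diag(10))                     # involution
  expect_true(all(rowSums(Q) == 1) && all(colSums(Q) == 1))
  expect_true(all(Q %in% c(0, 1)))
  expect_error(make_outside_Q("block_swap", 9), "even")
  # block permutation mirrors a column permutation on row blocks
  Qb <- make_outside_Q("block_permutation", 8, perm = c(2, 1, 4, 3))
  K <- matrix(1:16, 8, 2)
  expect_equal((Qb %*% K)[1:2, ], K[3:4, ])
  # swapping the halves decorrelates the encoder columns
  set.seed(3)
  K2 <- matrix(rnorm(2000), 1000, 2)
  Ks <- make_outside_Q("block_swap", 1000) %*% K2
  expect_lt(columnwise_similarity(K2, Ks), 0.1)       # vs 1 for identity
})

test_that("inside permutations enumerate D! - 1 matrices", {
  expect_length(enumerate_inside_permutations(2), 1)
  expect_length(enumerate_inside_permutations(3), 5)
  perms4 <- enumerate_inside_permutations(4)
  expect_length(perms4, 23)
  # deterministic order, all distinct, none the identity
  keys <- sapply(perms4, function(q) paste(attr(q, "perm"), collapse = ""))
  expect_equal(anyDuplicated(keys), 0)
  expect_false("1234" %in% keys)
  expect_error(enumerate_inside_permutations(7), "d <= 6")
})

test_that("EC perturbation identities hold exactly", {
  K <- 0.05 * unclass(draw_encoders("unit_sphere_rows", 100, 2, seed = 4))
  net <- build_ec_network(K)
  # inside permutation: identical weights
  p_in <- perturb_and_relearn(net, "inside_permutation", seed = 1)
  expect_lt(max(abs(p_in$W_new - p_in$W_old)), 1e-12)
  # any orthogonal inside transform: identical weights
  p_rot <- perturb_and_relearn(net, "inside_rot45", seed = 2)
  expect_lt(max(abs(p_rot$W_new - p_rot$W_old)), 1e-12)
  # outside block swap: exact conjugation by the permutation
  p_out <- perturb_and_relearn(net, "outside_block_swap", seed = 3)
  Q <- make_outside_Q("block_swap", 100)
  expect_lt(max(abs(p_out$W_new - Q %*% p_out$W_old %*% t(Q))), 1e-12)
  # identity restart: EC is deterministic, weights unchanged
  p_id <- perturb_and_relearn(net, "identity", seed = 4)
  expect_equal(p_id$W_new, p_id$W_old)
})

test_that("NEF relearning reproduces the inside/outside ordering", {
  net <- build_nef_network(250, 2, 800, seed = 5)
  corr_of <- function(kind) {
    p <- perturb_and_relearn(net, kind, seed = 6)
    weight_similarity(p$W_old, p$W_new)$pearson
  }
  c_id <- corr_of("identity")
  c_in <- corr_of("inside_permutation")
  c_out <- corr_of("outside_block_swap")
  c_re <- corr_of("redraw_K")
  expect_gt(c_id, 0.9)
  expect_gt(c_in, 0.8)
  expect_lt(abs(c_out), 0.25)
  expect_lt(abs(c_re), 0.25)
  expect_gt(c_in, c_out + 0.5)
})

test_that("perturbation results tidy into similarity rows", {
  net <- tiny_ec(n = 30, seed = 7)
  p <- perturb_and_relearn(net, "inside_gaussian", seed = 8)
  row <- tidy(p)
  expect_named(row, c("kind", "pearson", "frobenius"))
  expect_equal(row$kind, "inside_gaussian")
})
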