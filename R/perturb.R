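#' Inside-manifold perturbation matrices
#'
#' D x D transforms applied to the encoder columns (`K_new = K Q`),
#' preserving the spanned subspace when `Q` is invertible:
#' * `permutation`: a column permutation (for D = 2 the swap
#'   `[[0, 1], [1, 0]]`); pass `perm` to pick a specific one
#' * `rot45`: the planar rotation by pi/4 (D = 2)
#' * `gaussian`: i.i.d. standard-normal entries (non-orthogonal)
#' * `same_element`: all entries equal to one random value (rank 1,
#'   non-orthogonal)
#'
#' @param kind one of the above
#' @param d latent dimensionality (>= 2)
#' @param seed integer seed (random kinds)
#' @param perm optional explicit permutation of `1:d` for
#'   `kind = "permutation"`
#' @return a D x D matrix
#' @export
make_inside_Q <- function(kind = c("permutation", "rot45", "gaussian",
                                   "same_element"),
                          d = 2, seed = NULL, perm = NULL) {
  kind <- match.arg(kind)
  stopifnot(d >= 2)
  if (!is.null(seed)) withr::local_seed(seed)
  switch(kind,
    permutation = {
      if (is.null(perm)) perm <- c(2L, 1L, if (d > 2) 3:d)
      stopifnot(length(perm) == d, all(sort(perm) == 1:d))
      diag(d)[, perm, drop = FALSE]
    },
    rot45 = {
      stopifnot(d == 2)
      th <- pi / 4
      matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    },
    gaussian = matrix(rnorm(d * d), d, d),
    same_element = matrix(rnorm(1), d, d))
}

#' Outside-manifold perturbation matrices
#'
#' N x N row permutations applied to the encoders (`K_new = Q K`), moving
#' the neural modes out of the original subspace:
#' * `block_swap`: exchanges the first and last N/2 rows (requires even N)
#' * `block_permutation`: splits the rows into `n_blocks` equal blocks and
#'   permutes the blocks by `perm` (the row-space mirror of a column
#'   permutation)
#' * `random`: a uniformly random row permutation
#'
#' @param kind one of the above
#' @param n number of neurons
#' @param perm block permutation (for `block_permutation`)
#' @param n_blocks number of equal row blocks
#' @param seed integer seed (random kind)
#' @return an N x N 0/1 permutation matrix
#' @export
make_outside_Q <- function(kind = c("block_swap", "block_permutation",
                                    "random"),
                           n, perm = NULL, n_blocks = NULL, seed = NULL) {
  kind <- match.arg(kind)
  if (!is.null(seed)) withr::local_seed(seed)
  row_perm <- switch(kind,
    block_swap = {
      if (n %% 2 != 0) stop("block_swap requires an even N")
      c((n / 2 + 1):n, 1:(n / 2))
    },
    block_permutation = {
      stopifnot(!is.null(perm))
      if (is.null(n_blocks)) n_blocks <- length(perm)
      stopifnot(n %% n_blocks == 0, length(perm) == n_blocks)
      bs <- n / n_blocks
      as.integer(sapply(perm, function(b) ((b - 1) * bs + 1):(b * bs)))
    },
    random = sample.int(n))
  diag(n)[row_perm, , drop = FALSE]
}

#' All non-identity permutation matrices of dimension D
#'
#' @param d dimension (guarded at `d <= 6`)
#' @return a list of `d! - 1` permutation matrices in deterministic
#'   (lexicographic) order; each carries the permutation as attribute
#'   `perm`
#' @export
enumerate_inside_permutations <- function(d) {
  stopifnot(d >= 2, d <= 6)
  perms <- all_permutations(d)
  perms <- perms[!vapply(perms, function(p) all(p == 1:d), logical(1))]
  lapply(perms, function(p)
    structure(diag(d)[, p, drop = FALSE], perm = p))
}

all_permutations <- function(d) {
  if (d == 1) return(list(1L))
  out <- list()
  for (i in seq_len(d)) {
    rest <- all_permutations(d - 1)
    for (r in rest) {
      v <- integer(d)
      v[1] <- i
      v[-1] <- setdiff(1:d, i)[r]
      out[[length(out) + 1]] <- v
    }
  }
  out
}

#' Perturb the encoders of a trained network and relearn
#'
#' Applies an inside (`K Q`, D x D) or outside (`Q K`, N x N) perturbation
#' — or redraws `K` entirely — and re-runs the framework's full learning
#' or solve procedure from scratch with identical hyperparameters and
#' targets (only the learning-phase randomness is reseeded). Returns the
#' old and new feedback weight matrices `W = K Phi`; the static reservoir
#' is excluded from all comparisons.
#'
#' @param net a `force_net`, `nef_net`, `ec_net` or `dale_net`
#' @param kind one of `"identity"` (restart learning only),
#'   `"inside_permutation"`, `"inside_rot45"`, `"inside_gaussian"`,
#'   `"inside_same_element"`, `"outside_block_swap"`,
#'   `"outside_block_permutation"`, `"redraw_K"`
#' @param seed seed for the perturbation draw and the relearning phase
#' @param perm explicit permutation (inside permutation / outside block
#'   permutation)
#' @return a `perturbation_result` list: `W_old`, `W_new`, `K_new`,
#'   `kind`, `Q`, and the relearned network `net_new`
#' @export
perturb_and_relearn <- function(net, kind, seed = NULL, perm = NULL) {
  kinds <- c("identity", "inside_permutation", "inside_rot45",
             "inside_gaussian", "inside_same_element",
             "outside_block_swap", "outside_block_permutation", "redraw_K")
  kind <- match.arg(kind, kinds)
  K <- unclass(net$K)
  n <- nrow(K); d <- ncol(K)
  if (!is.null(seed)) withr::local_seed(seed)
  Q <- NULL
  K_new <- switch(kind,
    identity = K,
    inside_permutation = { Q <- make_inside_Q("permutation", d, perm = perm); K %*% Q },
    inside_rot45 = { Q <- make_inside_Q("rot45", d); K %*% Q },
    inside_gaussian = { Q <- make_inside_Q("gaussian", d); K %*% Q },
    inside_same_element = { Q <- make_inside_Q("same_element", d); K %*% Q },
    outside_block_swap = { Q <- make_outside_Q("block_swap", n); Q %*% K },
    outside_block_permutation = {
      Q <- make_outside_Q("block_permutation", n, perm = perm); Q %*% K },
    redraw_K = redraw_like(net))
  net_new <- relearn(net, K_new)
  structure(list(W_old = feedback_weights(net),
                 W_new = feedback_weights(net_new),
                 K_new = K_new, kind = kind, Q = Q, net_new = net_new),
            class = "perturbation_result")
}

redraw_like <- function(net) {
  K <- unclass(net$K)
  if (inherits(net, "force_net")) {
    scale <- max(abs(K))
    unclass(draw_encoders("uniform_box", nrow(K), ncol(K), scale = scale))
  } else {
    # fresh directions at the original mean row norm
    g <- mean(sqrt(rowSums(K^2)))
    g * unclass(draw_encoders("unit_sphere_rows", nrow(K), ncol(K)))
  }
}

#' Feedback weight component of a network (reservoir excluded)
#' @param net a framework network object
#' @export
feedback_weights <- function(net) {
  if (inherits(net, "force_net")) unclass(net$K) %*% net$Phi
  else net$W
}

relearn <- function(net, K_new) UseMethod("relearn")

#' @export
relearn.nef_net <- function(net, K_new) {
  nef_solve(K_new, net$tuning, d = ncol(K_new), n_eval = net$n_eval,
            tau_syn = net$tau_syn, ridge = net$ridge, A = net$A)
}

#' @export
relearn.ec_net <- function(net, K_new) {
  out <- build_ec_network(K_new, tau_syn = net$tau_syn, mu = net$mu,
                          nu = net$nu, tau_m = net$tau_m)
  if (!isTRUE(all.equal(net$Gamma, net$lambda * t(net$K),
                        check.attributes = FALSE))) {
    # dynamics had been applied; recover A from Gamma = (tau A + I) lambda K'
    A <- (net$Gamma %*% unclass(net$K) %*% solve(crossprod(unclass(net$K))) /
            net$lambda - diag(ncol(net$K))) / net$tau_syn
    out <- ec_dynamics_weights(out, A)
  }
  out
}

#' @export
relearn.force_net <- function(net, K_new) {
  force_train(K_new, net$Omega, net$schedule, net$params, net$dt,
              net$tau_syn)
}

#' @export
relearn.dale_net <- function(net, K_new) {
  dale_resolve(net, K_new)
}

#' Simulate a perturbed network and decode with the old readout
#'
#' Runs the perturbed closed-loop network with no structured input and
#' decodes the latents with the unperturbed decoders: after an inside
#' permutation the decoded latent traces appear permuted accordingly.
#'
#' @param pert a [perturb_and_relearn()] result for a `dale_net`
#' @param old_decoders the unperturbed network's D x N readout
#' @param duration,dt,seed see [simulate_dale()]
#' @return a latent trajectory tibble of the decoded latents
#' @export
readout_with_old_decoders <- function(pert, old_decoders, duration = 6,
                                      dt = 1e-3, seed = NULL) {
  simulate_dale(pert$net_new, duration = duration, dt = dt,
                decoders = old_decoders, seed = seed)$x_dec
}
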