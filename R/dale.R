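#' Random sign-constraint mask enforcing sparsity and Dale's law
#'
#' `C[i, j] = 0` with probability `xi` (the connection is forbidden);
#' otherwise the sign is set by the presynaptic column: `+1` for
#' excitatory neurons (`j <= eps_frac * N`), `-1` for inhibitory ones.
#'
#' @param n number of neurons
#' @param xi sparsity threshold in \[0, 1\] (fraction of forbidden entries)
#' @param eps_frac fraction of excitatory neurons in (0, 1)
#' @param seed integer seed
#' @return an N x N integer matrix of class `sign_mask` with attributes
#'   `xi`, `eps_frac`, `n_exc`
#' @export
make_constraint_mask <- function(n, xi = 0.75, eps_frac = 0.8, seed = NULL) {
  stopifnot(xi >= 0, xi <= 1, eps_frac > 0, eps_frac < 1)
  if (!is.null(seed)) withr::local_seed(seed)
  n_exc <- floor(eps_frac * n)
  R <- matrix(runif(n * n), n, n)
  C <- matrix(0L, n, n)
  allowed <- R >= xi
  sign_col <- rep(c(1L, -1L), c(n_exc, n - n_exc))
  C[allowed] <- rep(sign_col, each = n)[allowed]
  structure(C, xi = xi, eps_frac = eps_frac, n_exc = n_exc,
            class = c("sign_mask", "matrix", "array"))
}

#' NEF feedback target embedding (possibly nonlinear) latent dynamics
#'
#' For latent dynamics `dx/dt = f_dyn(x)` realized through exponential
#' synapses, the feedback must output `tau_syn * f_dyn(x) + x`; in the
#' linear case `f_dyn(x) = A x` this reduces to the decoder transform
#' `(tau_syn A + I)`.
#'
#' @param x M x D matrix of latent evaluation points
#' @param f_dyn function mapping a D-row matrix of states (columns) to
#'   their time derivatives
#' @param tau_syn seconds
#' @return M x D matrix of feedback targets
#' @export
nef_feedback_target <- function(x, f_dyn, tau_syn) {
  fx <- t(f_dyn(t(x)))
  tau_syn * fx + x
}

#' Sign-constrained direct weight optimization
#'
#' Solves, independently for each postsynaptic row,
#' `min || (diag(gains) K fb(x_target))_row - w . u ||^2` over the
#' evaluation set subject to the row's sign pattern: masked entries are
#' exactly zero and the others must match the sign in `C`. Implemented as
#' non-negative least squares after negating inhibitory columns and
#' deleting masked columns (gram-based active-set solver).
#'
#' @param K encoder matrix (N x D, unit-norm rows)
#' @param tuning a [calibrate_gain_bias()] result
#' @param f_dyn latent dynamics function (see [nef_feedback_target()]);
#'   `NULL` for the static integrator (`fb(x) = x`)
#' @param eval_points M x D evaluation matrix
#' @param C a [make_constraint_mask()] result
#' @param tau_syn seconds
#' @return a `constrained_weights` list: `W` (N x N), `residuals` (per
#'   row), `converged` (logical per row), `mask`
#' @export
solve_constrained_weights <- function(K, tuning, f_dyn, eval_points, C,
                                      tau_syn = 0.01) {
  K <- unclass(K)
  n <- nrow(K)
  stopifnot(nrow(C) == n, ncol(C) == n)
  act <- estimate_activities(tuning, K, eval_points)     # M x N, Hz
  fb <- if (is.null(f_dyn)) eval_points
        else nef_feedback_target(eval_points, f_dyn, tau_syn)
  Y <- (fb %*% t(K)) * rep(tuning$gains, each = nrow(fb)) # M x N targets
  res <- cpp_solve_constrained(act, Y, matrix(as.integer(C), n, n), 500L)
  if (any(res$converged == 0))
    warning(sum(res$converged == 0), " row solves did not converge")
  structure(list(W = res$W, residuals = as.numeric(res$residuals),
                 converged = res$converged == 1, mask = C,
                 tuning = tuning, K = K, tau_syn = tau_syn),
            class = "constrained_weights")
}

#' Summary statistics of a Daleian weight matrix
#'
#' Connection probabilities per presynaptic population (entries
#' numerically distinguishable from zero, `|w| > tol_frac * max|w|`),
#' per-neuron excitatory and inhibitory input sums and their correlation
#' (E/I balance), kurtosis of log absolute weights (Pearson and excess
#' conventions), and the singular-value spectrum.
#'
#' @param W an N x N weight matrix (or `constrained_weights`)
#' @param eps_frac fraction of excitatory (first) columns
#' @param tol_frac zero tolerance as a fraction of the largest magnitude
#' @return a `dale_stats` list; `glance()`able to a one-row tibble
#' @export
weight_statistics <- function(W, eps_frac = 0.8, tol_frac = 1e-9) {
  if (inherits(W, "constrained_weights")) W <- W$W
  n <- nrow(W)
  n_exc <- floor(eps_frac * n)
  tol <- tol_frac * max(abs(W))
  nz <- abs(W) > tol
  p_exc <- mean(nz[, seq_len(n_exc)])
  p_inh <- if (n_exc < n) mean(nz[, (n_exc + 1):n]) else NA_real_
  exc_in <- rowSums(pmax(W, 0))
  inh_in <- rowSums(pmax(-W, 0))
  ei_cor <- if (stats::sd(exc_in) > 0 && stats::sd(inh_in) > 0)
    stats::cor(exc_in, inh_in) else NA_real_
  lw <- log(abs(W[nz]))
  m2 <- mean((lw - mean(lw))^2); m4 <- mean((lw - mean(lw))^4)
  kurt <- m4 / m2^2
  sv <- svd(W, nu = 0, nv = 0)$d
  rank_tol <- max(dim(W)) * .Machine$double.eps * sv[1]
  structure(list(p_conn_exc = p_exc, p_conn_inh = p_inh,
                 ei_balance_cor = ei_cor,
                 log_weight_kurtosis = kurt,
                 log_weight_kurtosis_excess = kurt - 3,
                 singular_values = sv,
                 numerical_rank = sum(sv > rank_tol),
                 n_exc = n_exc, n = n, zero_tol = tol),
            class = "dale_stats")
}

#' Build the sparse Daleian oscillator network
#'
#' Full pipeline for the biologically constrained network: unit-sphere
#' encoders, 80-120 Hz tuning, a sparsity/Dale sign mask, evaluation
#' points over the latent box, and the sign-constrained row solves with
#' the 4-D limit-cycle dynamics as feedback target. Also solves plain
#' (unconstrained) readout decoders for decoding the latents.
#'
#' @param n,d network size (the study's full profile is N = 5000, D = 4;
#'   the desk profile N = 500)
#' @param n_eval evaluation points (full 40000, desk 4000)
#' @param xi,eps_frac mask parameters (see [make_constraint_mask()])
#' @param omega,alpha oscillator-field parameters; defaults give 2 Hz and
#'   4 Hz pairs with unit attracting amplitude
#' @param tau_syn,max_rates,ridge NEF parameters
#' @param seed integer seed (encoders, tuning, mask, evaluation points)
#' @return a `dale_net` object
#' @export
build_dale_network <- function(n = 500, d = 4, n_eval = 4000, xi = 0.75,
                               eps_frac = 0.8, omega = 2 * pi * 2,
                               alpha = 0.2, tau_syn = 0.01,
                               max_rates = c(80, 120), ridge = 0.01,
                               seed = NULL) {
  stopifnot(d == 4)
  if (!is.null(seed)) withr::local_seed(seed)
  K <- draw_encoders("unit_sphere_rows", n, d)
  tuning <- calibrate_gain_bias(n, max_rates)
  C <- make_constraint_mask(n, xi, eps_frac)
  ev <- sample_evaluation_points(d, n_eval)
  f_dyn <- function(x) oscillator_field(x, omega, alpha)
  cw <- solve_constrained_weights(K, tuning, f_dyn, ev, C, tau_syn)
  act <- estimate_activities(tuning, K, ev)
  Phi <- solve_decoders(act, ev, ridge)
  structure(list(K = K, tuning = tuning, mask = C, W = cw$W,
                 constrained = cw, Phi = Phi, omega = omega,
                 alpha = alpha, tau_syn = tau_syn, n_eval = n_eval,
                 eval_points = ev, f_dyn = f_dyn, ridge = ridge),
            class = c("dale_net", "manifold_net"))
}

# Re-solve the Daleian weights for new encoders under the same tuning,
# mask and evaluation points.
dale_resolve <- function(net, K_new, eval_seed = NULL) {
  ev <- if (is.null(eval_seed)) net$eval_points
        else sample_evaluation_points(ncol(net$K), net$n_eval,
                                      seed = eval_seed)
  cw <- solve_constrained_weights(K_new, net$tuning, net$f_dyn, ev,
                                  net$mask, net$tau_syn)
  out <- net
  out$K <- K_new
  out$W <- cw$W
  out$constrained <- cw
  out
}

#' Simulate the Daleian network in closed loop
#'
#' Current: `W u / tau_syn + biases` with no structured input; the latents
#' start near 0 and the oscillations self-start from spiking noise.
#' Decoding uses the supplied decoders (by default the network's own).
#'
#' @param net a `dale_net` object
#' @param duration,dt seconds
#' @param decoders D x N readout (e.g. the unperturbed network's `Phi`)
#' @param seed seed for initial voltages
#' @return list with `raster` and `x_dec` (latent trajectory tibble)
#' @export
simulate_dale <- function(net, duration = 6, dt = 1e-3, decoders = NULL,
                          seed = NULL) {
  n <- nrow(net$K)
  nt <- round(duration / dt)
  params <- net$tuning$params
  if (is.null(decoders)) decoders <- net$Phi
  if (!is.null(seed)) withr::local_seed(seed)
  v0 <- runif(n, params$v_reset, rep_len(params$v_th, n))
  res <- cpp_lif_sim(matrix(0, 0, 0), net$tuning$biases, net$W,
                     matrix(0, 0, 0), decoders, matrix(0, 0, 0),
                     integer(0), n, nt, dt, params$tau_m, net$tau_syn,
                     params$r_m, params$v_leak, rep_len(params$v_th, n),
                     params$v_reset, params$t_ref, v0, TRUE, 1L)
  raster <- new_spike_raster(res$spike_id, res$spike_time, n, duration)
  times <- seq_len(nt) * dt
  u <- filter_spikes(raster, net$tau_syn, dt)
  xd <- decoders %*% (u / net$tau_syn)
  list(raster = raster,
       x_dec = new_latent_traj(times, xd, rep(FALSE, nt)))
}

#' Zero-crossing frequency estimate of an oscillating trace
#'
#' Smooths the trace with a short boxcar (zero crossings of a noisy trace
#' are dominated by the noise otherwise), discards a transient, and
#' counts mean crossings: frequency = crossings / 2 / window.
#'
#' @param x numeric trace
#' @param dt seconds per sample
#' @param discard_s transient to drop from the start
#' @param smooth_s boxcar width in seconds (0 disables smoothing)
#' @return estimated frequency in Hz
#' @export
freq_zero_crossings <- function(x, dt, discard_s = 1, smooth_s = 0.025) {
  drop_n <- min(length(x) - 2, round(discard_s / dt))
  x <- x[(drop_n + 1):length(x)]
  k <- round(smooth_s / dt)
  if (k > 1) {
    x <- as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
    x <- x[!is.na(x)]
  }
  x <- x - mean(x)
  s <- sign(x)
  s <- s[s != 0]
  crossings <- sum(diff(s) != 0)
  crossings / 2 / (length(x) * dt)
}
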