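#' Build an Efficient Coding network with analytically fixed weights
#'
#' No learning: the readout is `Phi = lambda K'` with
#' `lambda = 1 / tau_syn`, the slow recurrent weights are
#' `W = lambda K K'`, and the fast (instantaneous) reservoir weights are
#' `Omega = -K K' - mu lambda^2 I`, whose inhibitory autapses implement
#' the reset (the voltage drops by `||k_j||^2 + mu lambda^2` after each
#' spike, so no explicit reset is applied). Per-neuron thresholds follow
#' `V_th,j = (nu lambda + mu lambda^2 + ||k_j||^2) / 2` (the halved
#' convention of the source network class; set `halve_threshold = FALSE`
#' for the unhalved variant).
#'
#' @param K encoder matrix (N x D)
#' @param tau_syn synaptic time constant, seconds (20 ms gives
#'   `lambda = 50` Hz)
#' @param mu quadratic firing-rate regularizer
#' @param nu linear firing-rate regularizer
#' @param tau_m membrane time constant, seconds
#' @param halve_threshold logical; see above
#' @return an `ec_net` object with `K`, `Phi`, `W` (slow), `Omega_fast`,
#'   `thresholds`, `lambda`
#' @export
build_ec_network <- function(K, tau_syn = 0.02, mu = 1e-6, nu = 1e-3,
                             tau_m = 0.05, halve_threshold = TRUE) {
  K <- unclass(K)
  stopifnot(all(is.finite(K)))
  lambda <- 1 / tau_syn
  KKt <- tcrossprod(K)
  k2 <- rowSums(K^2)
  thr <- nu * lambda + mu * lambda^2 + k2
  if (halve_threshold) thr <- thr / 2
  structure(list(K = K, Phi = lambda * t(K),
                 W = lambda * KKt,
                 Omega_fast = -KKt - mu * lambda^2 * diag(nrow(K)),
                 thresholds = thr, lambda = lambda,
                 tau_syn = tau_syn, tau_m = tau_m, mu = mu, nu = nu,
                 A = NULL, Gamma = lambda * t(K)),
            class = c("ec_net", "manifold_net"))
}

#' Slow weights implementing latent dynamics in the Efficient Coding net
#'
#' Applies the decoder transform explicitly: the feedback decoder becomes
#' `Gamma = (tau_syn A + I) lambda K'` and the slow weights `K Gamma`.
#'
#' @param net an `ec_net` object
#' @param A D x D latent dynamics matrix
#' @return the network with updated `Gamma` and slow `W`
#' @export
ec_dynamics_weights <- function(net, A) {
  stopifnot(inherits(net, "ec_net"), nrow(A) == ncol(net$K))
  Gamma <- dynamics_transform(A, net$Phi, net$tau_syn)
  net$Gamma <- Gamma
  net$W <- net$K %*% Gamma
  net$A <- A
  net
}

#' Simulate an Efficient Coding network
#'
#' The slow current is `K (Gamma u)`; during fixation windows the decoded
#' feedback is replaced by the clamped target, `K x_target`. Fast synapses
#' act as same-step voltage jumps, applied one spike at a time (largest
#' threshold overshoot first) before re-testing, which keeps the spiking
#' asynchronous. Latent targets are scaled by `latent_scale` internally
#' and the decoded output scaled back down.
#'
#' @param net an `ec_net` object
#' @param targets latent trajectory tibble (clamp values + length)
#' @param dt simulation step, seconds (0.1 ms recommended)
#' @param latent_scale internal scaling of the latent units (the study
#'   runs the latents 100x larger than plotted)
#' @param seed seed for the initial voltages and background noise
#' @param noise_frac stationary standard deviation of the background
#'   membrane-voltage noise, as a fraction of each neuron's threshold
#'   (the source network class runs with background noise; it spreads
#'   spiking across similarly tuned neurons)
#' @param max_spikes_per_step stability guard; exceeding it aborts with a
#'   runaway-rate error
#' @return list with `raster` and `x_dec` (plot-scale latent trajectory)
#' @export
simulate_ec <- function(net, targets, dt = 1e-4, latent_scale = 100,
                        seed = NULL, noise_frac = 0.1,
                        max_spikes_per_step = 500) {
  xt <- traj_matrix(targets) * latent_scale
  nt <- ncol(xt)
  n <- nrow(net$K)
  if (!is.null(seed)) withr::local_seed(seed)
  v0 <- runif(n, 0, 0.01 * net$thresholds)   # start near rest (V ~ 0)
  # clamp current replaces the decoded estimate in the slow-feedback slot
  TA <- if (is.null(net$A)) net$lambda * diag(ncol(net$K))
        else net$lambda * (net$tau_syn * net$A + diag(ncol(net$K)))
  # per-step innovation giving a stationary OU noise sd of noise_frac * V_th
  noise_sd <- noise_frac * net$thresholds * sqrt(2 * dt / net$tau_m)
  if (noise_frac == 0) noise_sd <- numeric(0)
  res <- cpp_ec_sim(net$K, net$Gamma, net$Omega_fast, net$thresholds,
                    TA %*% xt, as.integer(targets$fixed),
                    dt, net$tau_m, net$tau_syn, v0, noise_sd, 1L,
                    as.integer(max_spikes_per_step))
  duration <- nt * dt
  raster <- new_spike_raster(res$spike_id, res$spike_time, n, duration)
  xd <- new_latent_traj(targets$time, res$x_rec / latent_scale,
                        targets$fixed)
  mean_rate <- length(res$spike_id) / n / duration
  if (mean_rate > 1000)
    stop("runaway mean rate ", round(mean_rate), " Hz; increase mu or reduce dt")
  list(raster = raster, x_dec = xd, mean_rate_hz = mean_rate)
}
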