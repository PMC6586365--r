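#' Calibrate per-neuron gains and biases from max rates and intercepts
#'
#' Each neuron's drive is `J = gain * (k_j . x) + bias` with `k_j` its
#' (unit-norm) encoder row. Gains and biases are solved from two defining
#' conditions on the closed-form LIF rate: the rate is 0 at the intercept
#' along the preferred direction, and equals the drawn maximum rate at
#' `x = 1` along it. Max rates are drawn uniformly from `max_rates` and
#' intercepts uniformly from [-1, 1).
#'
#' @param n number of neurons
#' @param max_rates length-2 Hz interval (default 80-120 Hz)
#' @param params LIF parameters (NEF convention: `tau_m` 20 ms, `V_th` 1,
#'   `V_reset` 0, `t_ref` 2 ms)
#' @param seed integer seed
#' @return a `neuron_tuning` list: `gains`, `biases`, `max_rates`,
#'   `intercepts`, `params`
#' @export
calibrate_gain_bias <- function(n, max_rates = c(80, 120),
                                params = lif_params(), seed = NULL) {
  stopifnot(n >= 1, length(max_rates) == 2, max_rates[1] > 0)
  if (!is.null(seed)) withr::local_seed(seed)
  mr <- runif(n, max_rates[1], max_rates[2])
  ic <- runif(n, -1, 1)
  # invert the f-I curve: drive J_max giving rate mr
  if (any(1 / mr <= params$t_ref))
    stop("max rate exceeds the refractory ceiling 1/t_ref")
  # rate = 1/(t_ref + tau_m log((J - Vreset')/(J - Vth'))) with Vleak folded
  # normalized drive measured as V_inf = v_leak + r_m J; solve for V_inf:
  gap <- exp((1 / mr - params$t_ref) / params$tau_m)
  vth <- rep_len(params$v_th, n)
  vinf_max <- (vth * gap - params$v_reset) / (gap - 1)
  j_max <- (vinf_max - params$v_leak) / params$r_m
  j_th <- (vth - params$v_leak) / params$r_m    # drive at rheobase
  gains <- (j_max - j_th) / (1 - ic)
  biases <- j_th - gains * ic
  structure(list(gains = gains, biases = biases, max_rates = mr,
                 intercepts = ic, params = params),
            class = "neuron_tuning")
}

#' Sample evaluation points from the latent domain
#'
#' @param d latent dimensionality
#' @param m number of points
#' @param domain length-2 interval applied to every dimension
#' @param seed integer seed
#' @return an M x D matrix
#' @export
sample_evaluation_points <- function(d, m = 2000, domain = c(-1, 1),
                                     seed = NULL) {
  stopifnot(m >= d)
  if (!is.null(seed)) withr::local_seed(seed)
  matrix(runif(m * d, domain[1], domain[2]), m, d)
}

#' Expected activities at evaluation points
#'
#' `activities[m, j] = lif_rate(gain_j * (k_j . x_m) + bias_j)`, in Hz —
#' the expected value of the filtered spike train at each point, up to the
#' shot-noise factor `tau_syn` which the decoders absorb (the spiking
#' readout divides the traces by `tau_syn`).
#'
#' @param tuning a [calibrate_gain_bias()] result
#' @param K encoder matrix (N x D, unit-norm rows)
#' @param eval_points M x D matrix
#' @return M x N activity matrix (Hz)
#' @export
estimate_activities <- function(tuning, K, eval_points) {
  proj <- eval_points %*% t(unclass(K))                 # M x N
  drive <- sweep(sweep(proj, 2, tuning$gains, `*`), 2, tuning$biases, `+`)
  act <- lif_rate(as.numeric(drive), tuning$params)
  matrix(act, nrow(eval_points), nrow(K))
}

#' Batch least-squares decoders over evaluation points
#'
#' Minimizes the mean squared decoding error over the evaluation set with
#' ridge regularization: `Phi' = (A'A + lambda I)^{-1} A' Y` where
#' `lambda = (ridge * max(A))^2 * M`.
#'
#' @param activities M x N activity matrix
#' @param targets M x D target matrix (what the decode should produce at
#'   each evaluation point)
#' @param ridge regularization as a fraction of the maximum activity
#' @return the D x N decoder matrix
#' @export
solve_decoders <- function(activities, targets, ridge = 0.01) {
  if (is.null(dim(targets))) targets <- matrix(targets, ncol = 1)
  stopifnot(nrow(activities) == nrow(targets))
  m <- nrow(activities)
  G <- crossprod(activities)
  lambda <- (ridge * max(abs(activities)))^2 * m
  if (lambda == 0 && rcond(G) < 1e-14)
    stop("rank-deficient activities with ridge = 0")
  diag(G) <- diag(G) + lambda
  t(solve(G, crossprod(activities, targets)))
}

#' Decoder transform embedding linear latent dynamics
#'
#' Feeding back `Gamma u` instead of `Phi u` through exponential synapses
#' with time constant `tau_syn` makes the latent variables evolve as
#' `dx/dt = A x`, where `Gamma = (tau_syn A + I) Phi`.
#'
#' @param A D x D dynamics matrix (`A = 0` recovers the integrator)
#' @param Phi D x N decoder matrix
#' @param tau_syn seconds
#' @return the D x N transformed decoder `Gamma`
#' @export
dynamics_transform <- function(A, Phi, tau_syn) {
  stopifnot(nrow(A) == ncol(A), nrow(A) == nrow(Phi))
  (tau_syn * A + diag(nrow(A))) %*% Phi
}

#' Combine encoders, gains and decoders into the recurrent weight matrix
#'
#' `W = diag(gains) K decoders` (N x N, rank <= D): the per-neuron input
#' `gain_j * k_j . (decoders u)` written as one matrix multiplication.
#'
#' @param K encoder matrix (N x D)
#' @param decoders D x N decoder matrix (`Phi` or `Gamma`)
#' @param gains per-neuron gain vector (default all 1)
#' @return N x N weight matrix
#' @export
assemble_weights <- function(K, decoders, gains = NULL) {
  K <- unclass(K)
  stopifnot(ncol(K) == nrow(decoders), nrow(K) == ncol(decoders))
  W <- K %*% decoders
  if (!is.null(gains)) W <- W * gains    # row scaling
  W
}

#' Build an NEF network
#'
#' Draws unit-sphere encoders, calibrates gains/biases, samples evaluation
#' points, estimates activities and solves for the decoders — optionally
#' for a latent dynamical system `dx/dt = A x` via [dynamics_transform()]
#' (applied through the feedback target, which for the linear case equals
#' the explicit transform).
#'
#' @param n,d network size and latent dimensionality
#' @param n_eval number of evaluation points
#' @param max_rates Hz interval for the maximum rates
#' @param tau_syn synaptic time constant, seconds (NEF default 10 ms)
#' @param ridge decoder regularization (see [solve_decoders()])
#' @param A optional D x D latent dynamics matrix
#' @param seed integer seed controlling encoders, tuning and evaluation
#'   points
#' @param relearn_seed optional separate seed for the solve phase
#'   (evaluation-point sample), used when re-running the learning with
#'   everything else held fixed
#' @return an `nef_net` object with `K`, `tuning`, `Phi` (identity
#'   decoder), `Gamma` (feedback decoder incl. dynamics), `W`
#' @export
build_nef_network <- function(n = 1000, d = 2, n_eval = 2000,
                              max_rates = c(80, 120), tau_syn = 0.01,
                              ridge = 0.01, A = NULL, seed = NULL,
                              relearn_seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  K <- draw_encoders("unit_sphere_rows", n, d)
  tuning <- calibrate_gain_bias(n, max_rates)
  net <- nef_solve(K, tuning, d = d, n_eval = n_eval, tau_syn = tau_syn,
                   ridge = ridge, A = A,
                   eval_seed = relearn_seed)
  net
}

# Solve-phase of the NEF build, reusable for relearning with perturbed
# encoders under identical tuning/hyperparameters.
nef_solve <- function(K, tuning, d = ncol(K), n_eval = 2000, tau_syn = 0.01,
                      ridge = 0.01, A = NULL, eval_seed = NULL) {
  if (!is.null(eval_seed)) withr::local_seed(eval_seed)
  ev <- sample_evaluation_points(d, n_eval)
  act <- estimate_activities(tuning, K, ev)
  Phi <- solve_decoders(act, ev, ridge)
  Gamma <- if (is.null(A)) Phi else dynamics_transform(A, Phi, tau_syn)
  structure(list(K = K, tuning = tuning, Phi = Phi, Gamma = Gamma,
                 A = A, tau_syn = tau_syn, ridge = ridge,
                 n_eval = n_eval,
                 W = assemble_weights(K, Gamma, tuning$gains)),
            class = c("nef_net", "manifold_net"))
}

#' Simulate an NEF network in closed loop
#'
#' The recurrent current is `diag(gains) K x_fb + biases` where `x_fb` is
#' the decoded latent state `Gamma u / tau_syn` — or the clamped target
#' during fixation windows (a relay node that outputs the fixed values
#' while clamped and passes the decode through otherwise).
#'
#' @param net an `nef_net` object
#' @param targets latent trajectory tibble providing clamp values and the
#'   simulation length
#' @param dt simulation step (NEF default 1 ms)
#' @param seed seed for the initial voltages
#' @return list with `raster` (spike raster) and `x_dec` (decoded latents,
#'   a latent trajectory tibble at the simulation grid)
#' @export
simulate_nef <- function(net, targets, dt = 1e-3, seed = NULL) {
  xt <- traj_matrix(targets)
  nt <- ncol(xt)
  n <- nrow(net$K)
  d <- nrow(xt)
  params <- net$tuning$params
  if (!is.null(seed)) withr::local_seed(seed)
  v0 <- runif(n, params$v_reset, rep_len(params$v_th, n))
  Kg <- unclass(net$K) * net$tuning$gains
  res <- cpp_lif_sim(matrix(0, 0, 0), net$tuning$biases, matrix(0, 0, 0),
                     Kg, net$Gamma, xt, as.integer(targets$fixed),
                     n, nt, dt, params$tau_m, net$tau_syn, params$r_m,
                     params$v_leak, rep_len(params$v_th, n),
                     params$v_reset, params$t_ref, v0, TRUE, 1L)
  duration <- nt * dt
  raster <- new_spike_raster(res$spike_id, res$spike_time, n, duration)
  xd <- new_latent_traj(targets$time, res$x_rec[seq_len(d), , drop = FALSE],
                        targets$fixed)
  list(raster = raster, x_dec = xd)
}
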