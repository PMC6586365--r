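#' Sparse balanced echo-state reservoir
#'
#' Entries are zero with probability `1 - p_nonzero` and otherwise drawn
#' from `Normal(0, sigma^2)` with `sigma = G / sqrt(p_nonzero * N)` (so the
#' stated `G = 10`, `N = 1000`, `p = 0.1` give `sigma = 1`). Rows are then
#' balanced so the average input weight to each neuron is zero; balancing
#' subtracts each row's mean from its nonzero entries.
#'
#' @param n number of neurons
#' @param p_nonzero connection probability (0 < p <= 1)
#' @param G chaos gain
#' @param seed integer seed
#' @param balance_over balance the row mean over "nonzero" entries
#'   (default) or over "all" N entries
#' @return an N x N matrix of class `reservoir_matrix`
#' @export
build_reservoir <- function(n, p_nonzero = 0.1, G = 10, seed = NULL,
                            balance_over = c("nonzero", "all")) {
  stopifnot(p_nonzero > 0, p_nonzero <= 1, n >= 2)
  balance_over <- match.arg(balance_over)
  if (!is.null(seed)) withr::local_seed(seed)
  sigma <- G / sqrt(p_nonzero * n)
  mask <- matrix(runif(n * n) < p_nonzero, n, n)
  omega <- matrix(0, n, n)
  omega[mask] <- rnorm(sum(mask), 0, sigma)
  for (j in seq_len(n)) {
    if (balance_over == "nonzero") {
      nz <- mask[j, ]
      if (!any(nz)) next
      omega[j, nz] <- omega[j, nz] - sum(omega[j, ]) / sum(nz)
    } else {
      # subtract the full-row mean from every entry (denser, but exactly
      # zero-mean over all N inputs)
      omega[j, ] <- omega[j, ] - mean(omega[j, ])
    }
  }
  structure(omega, class = c("reservoir_matrix", "matrix", "array"),
            sparsity_p = p_nonzero, G = G)
}

#' One recursive-least-squares update of the decoders
#'
#' Reference (pure R) implementation of the FORCE update pair: with error
#' `e = Phi u - x_target`,
#' `P <- P - (P u u' P) / (1 + u' P u)` followed by
#' `Phi <- Phi - e (P u)'` using the updated `P`. The training loop uses
#' the same rule compiled; this version backs small problems and tests.
#'
#' @param state list with `P` (N x N), `Phi` (D x N)
#' @param u filtered spike-train vector (length N)
#' @param x decoded latent vector (length D); defaults to `Phi u`
#' @param x_target target latent vector (length D)
#' @return the updated state list
#' @export
rls_update <- function(state, u, x_target, x = NULL) {
  if (any(!is.finite(u))) stop("non-finite regressor in RLS update")
  if (is.null(x)) x <- as.numeric(state$Phi %*% u)
  Pu <- state$P %*% u
  den <- 1 + sum(u * Pu)
  P <- state$P - tcrossprod(Pu) / den
  Pu2 <- P %*% u
  e <- x - x_target
  Phi <- state$Phi - tcrossprod(e, Pu2)
  list(P = P, Phi = Phi)
}

#' Training schedule for FORCE learning
#'
#' The target pattern is repeated for `learn_s` seconds with RLS active,
#' followed by `free_s` seconds of free running (learning off, feedback
#' fully closed). During learning the feedback current is a blend
#' `ramp * K x_decoded + (1 - ramp) * K x_target`, with a linear ramp from
#' 0 to 1 over the first `ramp_frac` of the learning phase — the network is
#' first driven by the target, then the decoded feedback is gradually
#' reintroduced.
#'
#' @param target a latent trajectory tibble (one pattern cycle)
#' @param learn_s,free_s seconds
#' @param ramp_frac fraction of the learning phase over which the feedback
#'   ramp rises from 0 to 1
#' @param update_stride apply the RLS update every this many steps
#' @export
training_schedule <- function(target, learn_s = 45, free_s = 5,
                              ramp_frac = 0.8, update_stride = 10L) {
  stopifnot(learn_s >= 0, free_s >= 0, learn_s + free_s > 0,
            ramp_frac > 0, ramp_frac <= 1, update_stride >= 1)
  structure(list(target = target, learn_s = learn_s, free_s = free_s,
                 ramp_frac = ramp_frac, update_stride = as.integer(update_stride)),
            class = "training_schedule")
}

force_unroll_schedule <- function(schedule, dt) {
  target <- schedule$target
  xt <- traj_matrix(target)
  fixed <- target$fixed
  cyc <- ncol(xt)
  total_s <- schedule$learn_s + schedule$free_s
  nt <- round(total_s / dt)
  idx <- ((seq_len(nt) - 1L) %% cyc) + 1L
  learn_steps <- round(schedule$learn_s / dt)
  ramp <- rep(1, nt)
  if (learn_steps > 0) {
    ramp_up <- max(1, round(schedule$ramp_frac * learn_steps))
    ramp[seq_len(learn_steps)] <- pmin(seq_len(learn_steps) / ramp_up, 1)
  }
  list(x_target = xt[, idx, drop = FALSE],
       clamp = as.integer(fixed[idx]),
       learn = as.integer(seq_len(nt) <= learn_steps),
       ramp = ramp, nt = nt)
}

#' Train a FORCE network
#'
#' Simulates the reservoir + feedback network while recursive least
#' squares adapts the decoders `Phi` (initialized at 0, with helper matrix
#' `P(0) = p0 * I`). The total current is `Omega u + K x_fb` where `x_fb`
#' is the clamped target during fixation windows, and otherwise the
#' ramp-blended feedback of [training_schedule()].
#'
#' @param K encoder matrix (N x D)
#' @param reservoir reservoir matrix (N x N), see [build_reservoir()]
#' @param schedule a [training_schedule()]
#' @param params LIF parameters; default [lif_params_force()]
#' @param dt simulation step, seconds
#' @param tau_syn synaptic time constant, seconds
#' @param p0 RLS helper-matrix initialization scale (`P(0) = p0 I`)
#' @param seed seed for the initial membrane voltages
#' @return a `force_net` object: `K`, `Omega`, `Phi`, `W = K Phi`, the
#'   post-training free-running decode, the spike raster of the final
#'   free-running window, and diagnostics
#' @export
force_train <- function(K, reservoir, schedule, params = lif_params_force(),
                        dt = 5e-5, tau_syn = 0.02, p0 = 5e-6, seed = NULL) {
  n <- nrow(K)
  stopifnot(nrow(reservoir) == n, ncol(reservoir) == n)
  target_dt <- traj_dt(schedule$target)
  if (abs(target_dt - dt) > 1e-12)
    stop("schedule target must be sampled at the simulation dt")
  un <- force_unroll_schedule(schedule, dt)
  if (!is.null(seed)) withr::local_seed(seed)
  v0 <- runif(n, params$v_reset, max(params$v_th, params$v_reset + 1e-6))
  rec_stride <- max(1L, round(1e-3 / dt))     # record decode at 1 ms
  res <- cpp_force_train(unclass(reservoir), unclass(K), un$x_target,
                         un$ramp, un$clamp, un$learn,
                         schedule$update_stride, p0,
                         matrix(0, ncol(K), n),
                         dt, params$tau_m, tau_syn, params$r_m,
                         params$v_leak, params$v_th, params$v_reset,
                         params$t_ref, v0, rec_stride)
  if (res$max_silent_steps * dt > 0.1)
    warning("firing-rate collapse: network silent for ",
            signif(res$max_silent_steps * dt, 3), " s")
  total_s <- schedule$learn_s + schedule$free_s
  raster <- new_spike_raster(res$spike_id, res$spike_time, n, total_s)
  Phi <- res$Phi
  structure(list(K = K, Omega = reservoir, Phi = Phi,
                 W = unclass(K) %*% Phi,
                 tau_syn = tau_syn, dt = dt, params = params,
                 schedule = schedule,
                 x_dec = res$x_rec, rec_dt = rec_stride * dt,
                 raster = raster,
                 diagnostics = list(max_silent_s = res$max_silent_steps * dt,
                                    n_spikes = length(res$spike_id))),
            class = c("force_net", "manifold_net"))
}
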