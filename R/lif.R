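#' Leaky integrate-and-fire neuron parameters
#'
#' Normalized-unit LIF parameters shared by all three frameworks. The
#' membrane follows `tau_m dV/dt = (V_leak - V) + R_m I`; a spike is
#' emitted when `V >= V_th`, after which `V` is reset to `V_reset` and
#' clamped there for the refractory time `t_ref`.
#'
#' @param tau_m membrane time constant, seconds
#' @param r_m membrane resistance (normalized units)
#' @param v_th spike threshold; a scalar or a per-neuron vector
#' @param v_reset reset voltage (`v_reset <= v_th`)
#' @param v_leak leak/rest voltage
#' @param t_ref absolute refractory period, seconds
#' @return a `lif_params` list
#' @export
lif_params <- function(tau_m = 0.02, r_m = 1, v_th = 1, v_reset = 0,
                       v_leak = 0, t_ref = 0.002) {
  stopifnot(tau_m > 0, t_ref >= 0, all(v_reset <= v_th))
  structure(list(tau_m = tau_m, r_m = r_m, v_th = v_th,
                 v_reset = v_reset, v_leak = v_leak, t_ref = t_ref),
            class = "lif_params")
}

#' FORCE-convention LIF parameters
#'
#' `R_m = 1`, `V_th = 0`, `V_reset = -1`, `V_leak = 0`: placing the rest
#' potential at threshold makes the neurons tonically active without a
#' driving current.
#' @param tau_m,t_ref seconds
#' @export
lif_params_force <- function(tau_m = 0.01, t_ref = 0.002) {
  lif_params(tau_m = tau_m, r_m = 1, v_th = 0, v_reset = -1,
             v_leak = 0, t_ref = t_ref)
}

new_spike_raster <- function(neuron, time, n_neurons, duration) {
  out <- tibble::tibble(neuron = as.integer(neuron), time = as.numeric(time))
  attr(out, "n_neurons") <- as.integer(n_neurons)
  attr(out, "duration") <- as.numeric(duration)
  class(out) <- c("spike_raster", class(out))
  out
}

#' Build a spike raster tibble from event vectors
#'
#' A spike raster is a tibble with integer column `neuron` (1-based) and
#' numeric column `time` (seconds), carrying `n_neurons` and `duration`
#' attributes.
#'
#' @param neuron,time parallel event vectors
#' @param n_neurons,duration raster extent
#' @export
spike_raster <- function(neuron, time, n_neurons, duration) {
  stopifnot(length(neuron) == length(time),
            all(neuron >= 1), all(neuron <= n_neurons),
            all(time >= 0), all(time <= duration + 1e-9))
  new_spike_raster(neuron, time, n_neurons, duration)
}

#' Causal exponential synaptic kernel
#'
#' `H(t) = exp(-t / tau_syn)` for `t >= 0`, and 0 for `t < 0`.
#' @param t time(s), seconds (vectorized)
#' @param tau_syn synaptic time constant, seconds
#' @export
exp_kernel <- function(t, tau_syn) {
  stopifnot(tau_syn > 0)
  ifelse(t < 0, 0, exp(-t / tau_syn))
}

#' Synaptically filtered spike trains
#'
#' Convolves each neuron's spike train with the exponential kernel on a
#' uniform grid: `u <- u * exp(-dt/tau_syn)` each step, incremented by 1 at
#' spike times.
#'
#' @param raster a spike raster tibble
#' @param tau_syn synaptic time constant, seconds
#' @param dt grid step, seconds (`dt < tau_syn`)
#' @return an N x T matrix of filtered traces with attributes `tau_syn`,
#'   `dt`
#' @export
filter_spikes <- function(raster, tau_syn, dt) {
  stopifnot(dt > 0, dt < tau_syn)
  n <- attr(raster, "n_neurons")
  dur <- attr(raster, "duration")
  nt <- round(dur / dt)
  counts <- matrix(0, n, nt)
  if (nrow(raster) > 0) {
    step <- pmin(pmax(ceiling(raster$time / dt - 1e-9), 1L), nt)
    idx <- cbind(raster$neuron, step)
    for (i in seq_len(nrow(idx)))
      counts[idx[i, 1], idx[i, 2]] <- counts[idx[i, 1], idx[i, 2]] + 1
  }
  decay <- exp(-dt / tau_syn)
  u <- t(apply(counts, 1, function(row)
    as.numeric(stats::filter(row, decay, method = "recursive"))))
  if (n == 1) u <- matrix(u, 1, nt)
  structure(u, tau_syn = tau_syn, dt = dt)
}

#' Bin spikes into consecutive fixed-width count windows
#'
#' Bins are left-closed, right-open; a trailing partial bin is dropped.
#'
#' @param raster a spike raster tibble
#' @param bin_width seconds (the study uses 50 ms)
#' @return an N x B integer count matrix of class `binned_rates` with a
#'   `bin_width` attribute
#' @export
bin_spikes <- function(raster, bin_width = 0.05) {
  stopifnot(bin_width > 0)
  n <- attr(raster, "n_neurons")
  dur <- attr(raster, "duration")
  nb <- floor(dur / bin_width + 1e-9)
  counts <- matrix(0L, n, nb)
  if (nrow(raster) > 0) {
    b <- floor(raster$time / bin_width) + 1L
    keep <- b <= nb & raster$time < nb * bin_width
    tb <- table(factor(raster$neuron[keep], levels = seq_len(n)),
                factor(b[keep], levels = seq_len(nb)))
    counts <- matrix(as.integer(tb), n, nb)
  }
  structure(counts, bin_width = bin_width, class = c("binned_rates", "matrix", "array"))
}

#' Stationary firing rate of an LIF neuron under constant drive
#'
#' Closed-form f-I curve: 0 below the effective threshold, otherwise
#' `1 / (t_ref + tau_m * log((V_inf - V_reset) / (V_inf - V_th)))` with
#' `V_inf = V_leak + R_m * I`. Used to calibrate NEF gains/biases and to
#' estimate expected activities at evaluation points.
#'
#' @param drive constant input current (vectorized)
#' @param params a [lif_params()] object
#' @param v_th optional per-call threshold override (vectorized with drive)
#' @return firing rate(s) in Hz
#' @export
lif_rate <- function(drive, params, v_th = NULL) {
  vth <- if (is.null(v_th)) params$v_th else v_th
  vinf <- params$v_leak + params$r_m * drive
  above <- vinf > vth
  rate <- numeric(length(vinf))
  num <- vinf - params$v_reset
  den <- vinf - vth
  rate[above] <- 1 / (params$t_ref +
                        params$tau_m * log(num[above] / den[above]))
  rate
}

#' Simulate a population of LIF neurons
#'
#' Exponential-Euler integration of the membrane equation with per-step
#' spike detection (spike-time resolution = `dt`), refractory clamping and
#' exponential synaptic filtering of the emitted spikes.
#'
#' @param current an N x T matrix of input currents, or a function
#'   `f(t)` returning the length-N current vector at time `t`
#' @param params a [lif_params()] object
#' @param duration,dt seconds
#' @param tau_syn synaptic time constant for the returned filtered traces
#' @param v0 initial voltages (default: all at `v_reset`)
#' @param record_stride record decoded/filtered output every this many
#'   steps (internal use)
#' @return a list with `raster` (spike raster tibble) and `u` (N x T
#'   filtered traces at the simulation grid is omitted; use
#'   [filter_spikes()] on the raster), plus `u_final`, `v_final`
#' @export
simulate_lif <- function(current, params, duration, dt, tau_syn = 0.02,
                         v0 = NULL) {
  stopifnot(dt > 0, duration > 0)
  nt <- round(duration / dt)
  if (is.function(current)) {
    times <- (seq_len(nt) - 1) * dt
    current <- vapply(times, current, numeric(length(current(0))))
    if (is.null(dim(current))) current <- matrix(current, 1)
  }
  stopifnot(is.matrix(current), ncol(current) == nt)
  if (any(!is.finite(current))) {
    bad <- which(colSums(!is.finite(current)) > 0)[1]
    stop("non-finite current at step ", bad)
  }
  n <- nrow(current)
  vth <- rep_len(params$v_th, n)
  if (is.null(v0)) v0 <- rep(params$v_reset, n)
  res <- cpp_lif_sim(current, rep(0, n), matrix(0, 0, 0), matrix(0, 0, 0),
                     matrix(0, 0, 0), matrix(0, 0, 0), integer(0),
                     n, nt, dt, params$tau_m, tau_syn, params$r_m,
                     params$v_leak, vth, params$v_reset, params$t_ref,
                     v0, FALSE, 0L)
  list(raster = new_spike_raster(res$spike_id, res$spike_time, n, duration),
       u_final = as.numeric(res$u_final),
       v_final = as.numeric(res$v_final))
}

#' Keep a random subset of neurons from a binned count matrix
#'
#' @param rates a `binned_rates` matrix (neurons x bins)
#' @param m number of neurons to keep (`m <= N`)
#' @param seed integer seed
#' @export
subsample_neurons <- function(rates, m, seed = NULL) {
  stopifnot(m <= nrow(rates), m >= 1)
  if (!is.null(seed)) withr::local_seed(seed)
  keep <- sort(sample.int(nrow(rates), m))
  structure(rates[keep, , drop = FALSE],
            bin_width = attr(rates, "bin_width"),
            neurons = keep,
            class = class(rates))
}

#' Serialize a spike raster as a two-column delimited event table
#' @param raster spike raster tibble
#' @param path file path
#' @export
write_raster <- function(raster, path) {
  utils::write.table(as.data.frame(raster)[c("neuron", "time")], path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
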