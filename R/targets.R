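#' Latent target trajectories and encoder matrices
#'
#' The study's networks are driven by low-dimensional latent targets and a
#' random encoder matrix `K` (N x D) whose columns span the intrinsic
#' manifold. Everything here is generated in code with seeded randomness;
#' there is no external data.
#'
#' A latent trajectory is a tibble with one row per time step and columns
#' `time`, `x1` ... `xD`, and `fixed` (TRUE while the latent variables are
#' externally clamped to the target values).
#'
#' @name latent_trajectory
NULL

new_latent_traj <- function(times, values, fixed) {
  stopifnot(is.matrix(values), ncol(values) == length(times),
            length(fixed) == length(times))
  d <- nrow(values)
  out <- tibble::tibble(time = as.numeric(times))
  for (i in seq_len(d)) out[[paste0("x", i)]] <- as.numeric(values[i, ])
  out$fixed <- as.logical(fixed)
  class(out) <- c("latent_traj", class(out))
  out
}

#' Extract the D x T latent-value matrix from a trajectory tibble
#' @param traj a latent trajectory tibble (see [make_step_targets()])
#' @return a D x T numeric matrix, one row per latent variable
#' @export
traj_matrix <- function(traj) {
  cols <- grep("^x[0-9]+$", names(traj), value = TRUE)
  t(as.matrix(traj[cols]))
}

#' Number of latent dimensions of a trajectory
#' @inheritParams traj_matrix
#' @export
traj_dims <- function(traj) length(grep("^x[0-9]+$", names(traj)))

traj_dt <- function(traj) {
  dt <- diff(traj$time)
  stopifnot(all(dt > 0), diff(range(dt)) < 1e-9 * dt[1])
  dt[1]
}

#' Piecewise-constant step targets with periodic fixation windows
#'
#' Emulates the evaluation protocol in which, every `period` seconds, the
#' latent variables are externally fixed to fresh random values for
#' `fix_len` seconds and then released; between fixations the reference
#' signal holds the last clamped value (the network is expected to retain
#' it, i.e. behave as a line attractor).
#'
#' @param d number of latent variables
#' @param duration total length in seconds; must be a multiple of `period`
#' @param dt time step in seconds
#' @param period seconds between the starts of consecutive fixations
#' @param fix_len seconds each fixation lasts (first part of each period)
#' @param value_range length-2 numeric; clamp values are drawn uniformly
#'   from this interval
#' @param seed integer seed; identical seeds give identical trajectories
#' @return a latent trajectory tibble (`time`, `x1`..`xD`, `fixed`)
#' @export
#' @examples
#' make_step_targets(2, duration = 2.5, dt = 0.001, seed = 1)
make_step_targets <- function(d, duration, dt, period = 0.5, fix_len = 0.1,
                              value_range = c(-1, 1), seed = NULL) {
  stopifnot(d >= 1, duration > 0, dt > 0, period > 0,
            fix_len > 0, fix_len <= period)
  n_per <- round(duration / period)
  if (abs(n_per * period - duration) > 1e-9)
    stop("`duration` must be a multiple of `period`")
  if (!is.null(seed)) withr::local_seed(seed)
  times <- seq(0, duration - dt / 2, by = dt)
  nt <- length(times)
  vals <- matrix(runif(d * n_per, value_range[1], value_range[2]), d, n_per)
  per_idx <- pmin(floor(times / period) + 1L, n_per)
  values <- vals[, per_idx, drop = FALSE]
  phase <- times - (per_idx - 1L) * period
  fixed <- phase < fix_len - 1e-12     # left-closed fixation window
  new_latent_traj(times, values, fixed)
}

#' Two-dimensional harmonic oscillator targets
#'
#' `x1 = amplitude * cos(2 pi f t)`, `x2 = amplitude * sin(2 pi f t)`; the
#' pair satisfies `dx/dt = A x` with the antisymmetric rotation generator
#' `A = [[0, -w], [w, 0]]`, `w = 2 pi f`.
#'
#' @param f_hz oscillation frequency in Hz (`f = 0` gives a constant)
#' @param duration,dt seconds
#' @param amplitude oscillation amplitude (latent units)
#' @return a latent trajectory tibble with D = 2 and `fixed` all FALSE
#' @export
make_oscillator_targets <- function(f_hz, duration, dt, amplitude = 1) {
  stopifnot(f_hz >= 0, duration > 0, dt > 0)
  times <- seq(0, duration - dt / 2, by = dt)
  w <- 2 * pi * f_hz
  values <- rbind(amplitude * cos(w * times), amplitude * sin(w * times))
  new_latent_traj(times, values, rep(FALSE, length(times)))
}

#' Rotation generator of a planar oscillator
#'
#' @param f_hz frequency in Hz
#' @return the 2 x 2 antisymmetric matrix `[[0, -w], [w, 0]]`, `w = 2 pi f`
#' @export
oscillator_A <- function(f_hz) {
  w <- 2 * pi * f_hz
  matrix(c(0, w, -w, 0), 2, 2)
}

#' Draw a random encoder matrix K
#'
#' `K` (N x D) maps latent variables to per-neuron feedback currents; its
#' columns set the intrinsic manifold. Two schemes are used by the three
#' frameworks: i.i.d. uniform entries on `[-scale, scale]` (FORCE) and rows
#' drawn uniformly from the unit sphere (NEF / Efficient Coding).
#'
#' @param scheme "uniform_box" or "unit_sphere_rows"
#' @param n,d numbers of neurons and latent dimensions (`n >= d >= 1`)
#' @param scale half-width of the uniform box (ignored for the sphere)
#' @param seed integer seed
#' @return an N x D numeric matrix of class `encoder_matrix`
#' @export
draw_encoders <- function(scheme = c("uniform_box", "unit_sphere_rows"),
                          n, d, scale = 100, seed = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(n >= d, d >= 1)
  if (!is.null(seed)) withr::local_seed(seed)
  k <- switch(scheme,
    uniform_box = matrix(runif(n * d, -scale, scale), n, d),
    unit_sphere_rows = {
      g <- matrix(rnorm(n * d), n, d)
      nrm <- sqrt(rowSums(g^2))
      while (any(nrm < 1e-12)) {         # essentially impossible, but be safe
        bad <- nrm < 1e-12
        g[bad, ] <- matrix(rnorm(sum(bad) * d), ncol = d)
        nrm <- sqrt(rowSums(g^2))
      }
      g / nrm
    })
  structure(k, class = c("encoder_matrix", "matrix", "array"),
            scheme = scheme)
}

#' Vector field of the 4-D nonlinear oscillator
#'
#' Two planar oscillators (frequencies `w` and `2 w` rad/s, i.e. a 2 Hz and
#' a 4 Hz pair at the default) whose radii are pulled toward 1 by the term
#' `alpha * (1 - r^2) * x` in each plane. This is the latent dynamics used
#' by the Daleian network.
#'
#' @param x numeric 4-vector (or 4-row matrix of states in columns)
#' @param omega angular frequency of the slow pair, rad/s
#' @param alpha radial stabilisation gain (unitless); `alpha > 0` makes the
#'   unit circles attracting
#' @return the time derivative, same shape as `x`
#' @export
oscillator_field <- function(x, omega = 2 * pi * 2, alpha = 0.2) {
  x <- if (is.matrix(x)) x else matrix(x, 4, 1)
  stopifnot(nrow(x) == 4)
  r1 <- x[1, ]^2 + x[2, ]^2
  r2 <- x[3, ]^2 + x[4, ]^2
  out <- rbind(
     omega * x[2, ] + alpha * (1 - r1) * x[1, ],
    -omega * x[1, ] + alpha * (1 - r1) * x[2, ],
     2 * omega * x[4, ] + alpha * (1 - r2) * x[3, ],
    -2 * omega * x[3, ] + alpha * (1 - r2) * x[4, ])
  if (ncol(out) == 1) drop(out) else out
}

#' Reference trajectory of the 4-D limit-cycle system
#'
#' Integrates [oscillator_field()] with a fixed-step classical Runge-Kutta
#' scheme at the simulation time step, so reference trajectories align with
#' the spiking grid.
#'
#' @param omega,alpha see [oscillator_field()]
#' @param x0 initial 4-vector
#' @param duration,dt seconds; `dt * omega` must be small for stability
#' @return a latent trajectory tibble with D = 4
#' @export
limit_cycle_reference <- function(omega = 2 * pi * 2, alpha = 0.2,
                                  x0 = c(1, 0, 1, 0), duration = 5, dt = 1e-3) {
  stopifnot(length(x0) == 4, duration > 0, dt > 0)
  times <- seq(0, duration - dt / 2, by = dt)
  nt <- length(times)
  values <- matrix(0, 4, nt)
  x <- as.numeric(x0)
  f <- function(x) oscillator_field(x, omega, alpha)
  for (i in seq_len(nt)) {
    values[, i] <- x
    k1 <- f(x); k2 <- f(x + dt / 2 * k1)
    k3 <- f(x + dt / 2 * k2); k4 <- f(x + dt * k3)
    x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (any(!is.finite(x)) || sqrt(sum(x^2)) > 1e3)
      stop("limit-cycle integration diverged at t = ", signif(times[i], 4))
  }
  new_latent_traj(times, values, rep(FALSE, nt))
}

#' Serialize / read a latent trajectory as delimited text
#'
#' Columns: `time`, `x1`..`xD`, `fixed` (0/1), tab-separated.
#' @param traj a latent trajectory tibble
#' @param path file path
#' @export
write_trajectory <- function(traj, path) {
  df <- as.data.frame(traj)
  df$fixed <- as.integer(df$fixed)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  cols <- grep("^x[0-9]+$", names(df), value = TRUE)
  new_latent_traj(df$time, t(as.matrix(df[cols])), df$fixed != 0)
}
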