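# Small in-code fixtures shared across test files.

tiny_nef <- function(n = 80, d = 2, n_eval = 400, seed = 11, ...) {
  build_nef_network(n, d, n_eval, seed = seed, ...)
}

tiny_ec <- function(n = 60, d = 2, seed = 5, norm = 1) {
  K <- norm * unclass(draw_encoders("unit_sphere_rows", n, d, seed = seed))
  build_ec_network(K)
}

# Constant-rate Poisson raster
poisson_raster <- function(n, rate_hz, duration, seed) {
  withr::local_seed(seed)
  events <- lapply(seq_len(n), function(j) {
    k <- rpois(1, rate_hz * duration)
    sort(runif(k, 0, duration))
  })
  spike_raster(rep(seq_len(n), lengths(events)), unlist(events),
               n, duration)
}

# Brute-force NNLS: enumerate active sets, keep the feasible optimum.
brute_nnls <- function(A, b) {
  p <- ncol(A)
  best <- rep(0, p)
  best_obj <- sum(b^2)
  for (mask in 0:(2^p - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(p) - 1)) > 0)
    if (length(idx) == 0) next
    z <- tryCatch(qr.solve(A[, idx, drop = FALSE], b), error = function(e) NULL)
    if (is.null(z) || any(z < -1e-12)) next
    r <- b - A[, idx, drop = FALSE] %*% z
    if (sum(r^2) < best_obj - 1e-12) {
      best_obj <- sum(r^2)
      best <- rep(0, p)
      best[idx] <- z
    }
  }
  best
}
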