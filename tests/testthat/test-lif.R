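test_that("exponential kernel is causal with unit peak", {
  expect_equal(exp_kernel(0, 0.02), 1)
  expect_equal(exp_kernel(-1, 0.02), 0)
  expect_equal(exp_kernel(0.02, 0.02), exp(-1))
  expect_equal(exp_kernel(c(-0.5, 0, 0.04), 0.02), c(0, 1, exp(-2)))
})

test_that("filter_spikes matches the kernel convolution", {
  # empty raster
  r0 <- spike_raster(integer(0), numeric(0), 3, 1)
  expect_equal(max(abs(filter_spikes(r0, 0.02, 1e-3))), 0)
  # single spike: impulse response
  r1 <- spike_raster(1L, 0.1, 1, 1)
  u <- filter_spikes(r1, 0.02, 1e-3)
  tt <- (1:1000) * 1e-3
  expected <- ifelse(tt < 0.1, 0, exp(-(tt - 0.1) / 0.02))
  expect_equal(as.numeric(u), expected, tolerance = 1e-9)
  # Poisson train: mean(u) -> rate * tau_syn (shot-noise expectation)
  rate <- 80; tau <- 0.02
  r2 <- poisson_raster(20, rate, 10, seed = 4)
  u2 <- filter_spikes(r2, tau, 1e-3)
  m <- mean(u2[, 200:10000])
  se <- stats::sd(rowMeans(u2[, 200:10000])) / sqrt(20)
  expect_lt(abs(m - rate * tau), 3 * se)
})

test_that("bin_spikes counts left-closed windows and drops the tail", {
  r <- spike_raster(c(1L, 2L, 3L, 1L), c(0.01, 0.02, 0.049, 0.12), 3, 0.13)
  b <- bin_spikes(r, 0.05)
  expect_equal(ncol(b), 2)                      # trailing partial bin dropped
  expect_equal(as.integer(b[, 1]), c(1L, 1L, 1L))
  expect_equal(sum(b), 3)                       # the 0.12 s spike is in the tail
  # 2.5 s at 50 ms -> 50 bins
  r2 <- spike_raster(1L, 1.0, 1, 2.5)
  expect_equal(ncol(bin_spikes(r2, 0.05)), 50)
})

test_that("simulated LIF rates match the closed-form f-I curve", {
  p <- lif_params(tau_m = 0.02, v_th = 1, v_reset = 0, t_ref = 0.002)
  # subthreshold drive: silent
  sub <- simulate_lif(matrix(0.9, 2, 1000), p, 1, 1e-3)
  expect_equal(nrow(sub$raster), 0)
  expect_equal(lif_rate(0.9, p), 0)
  expect_equal(lif_rate(1, p), 0)              # continuous from below
  # suprathreshold: within 2% of the closed form at several drives
  for (I in c(1.3, 2, 4)) {
    sim <- simulate_lif(matrix(I, 1, 50000), p, 5, 1e-4)
    expect_equal(nrow(sim$raster) / 5, lif_rate(I, p), tolerance = 0.02)
  }
  # monotonicity of the f-I curve
  rates <- lif_rate(seq(0.5, 5, by = 0.1), p)
  expect_true(all(diff(rates) >= 0))
})

test_that("refractory invariant holds in generated rasters", {
  p <- lif_params(tau_m = 0.02, v_th = 1, v_reset = 0, t_ref = 0.005)
  sim <- simulate_lif(matrix(runif(5 * 4000, 1.2, 3), 5, 4000), p, 4, 1e-3)
  isi <- with(sim$raster, tapply(time, neuron, function(t) min(diff(t))))
  expect_true(all(isi >= 0.005 - 1e-9))
})

test_that("non-finite currents raise a simulation error naming the step", {
  p <- lif_params()
  bad <- matrix(1, 1, 100); bad[1, 7] <- NaN
  expect_error(simulate_lif(bad, p, 0.1, 1e-3), "step 7")
})

test_that("FORCE normalization fires with any positive drive", {
  p <- lif_params_force()
  sim <- simulate_lif(matrix(0.05, 1, 20000), p, 2, 1e-4)
  expect_gt(nrow(sim$raster), 10)   # tonically active
  r <- lif_rate(0.05, p)
  expect_equal(nrow(sim$raster) / 2, r, tolerance = 0.02)
})

test_that("neuron subsampling preserves counts and is seeded", {
  r <- poisson_raster(30, 20, 2, seed = 8)
  b <- bin_spikes(r, 0.05)
  s1 <- subsample_neurons(b, 10, seed = 1)
  s2 <- subsample_neurons(b, 10, seed = 1)
  expect_identical(unclass(s1), unclass(s2))
  expect_equal(nrow(s1), 10)
  full <- subsample_neurons(b, 30, seed = 2)
  expect_equal(sort(attr(full, "neurons")), 1:30)
  expect_error(subsample_neurons(b, 31, seed = 1))
})
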