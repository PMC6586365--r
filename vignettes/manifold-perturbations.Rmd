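---
title: "Neural modes, connectivity, and manifold perturbations in spiking networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neural modes, connectivity, and manifold perturbations in spiking networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuromodes)
```

## The scientific question

Population activity recorded from cortex is usually low dimensional: the
N-dimensional vector of firing rates stays close to a D-dimensional linear
subspace (the *intrinsic manifold*), with D much smaller than N. Writing
the binned activity as `a(t) = Z x(t) + noise`, the columns of `Z` are the
*neural modes* and the coefficients `x(t)` the *latent variables*.
Brain-computer-interface experiments show that animals quickly learn
readout perturbations that stay inside this manifold but struggle with
perturbations that require activity outside it.

`neuromodes` builds spiking networks in which the manifold is a direct
consequence of the recurrent connectivity. A decoder `Phi` (D x N) reads
the latent variables from synaptically filtered spike trains,
`x = Phi u`, and an encoder `K` (N x D) feeds them back as input
currents. Because both steps are linear they collapse into one weight
matrix

```
W = K Phi        (N x N, rank <= D)
```

so the encoder columns fix the modes and the network behaves as a
D-dimensional line attractor. The package then asks the study's central
question quantitatively: if the modes are perturbed by a D x D transform
(`K -> K Q`, *inside-manifold*) or an N x N row permutation
(`K -> Q K`, *outside-manifold*), how much must `W` change after
relearning? For orthogonal inside transforms
`W_new = K Q (Q' Phi) = W`, so almost nothing; for outside permutations
`W_new = Q W Q'`, which shares essentially no structure with `W`.

## The three construction frameworks

All frameworks use leaky integrate-and-fire neurons,
`tau_m dV/dt = (V_leak - V) + R_m I`, with exponential synapses
`H(t) = exp(-t / tau_syn)`.

**FORCE (echo-state reservoir + recursive least squares).** A sparse
random reservoir `Omega` (connection probability 0.1, Normal entries with
sd `G / sqrt(0.1 N)`, `G = 10`, rows balanced to zero mean) keeps the
network active; the total current is `Omega u + K x_fb`. The decoders are
adapted online while the network runs: every 10th step
`P <- P - (P u u' P) / (1 + u' P u)` and `Phi <- Phi - e (P u)'` with
`e = Phi u - x_target` and `P(0) = 5e-6 I`. Neuron normalization
`R_m = 1, V_th = 0, V_reset = -1, V_leak = 0`; `tau_m` 10 ms, `tau_syn`
20 ms, `t_ref` 2 ms; encoders uniform on [-100, 100]. Training first
drives the network with the target ("teacher forcing"), then a linear
ramp re-introduces the decoded feedback over the first 80% of the
learning phase — the written protocol only requires a gradual
reintroduction, and any monotone ramp reaching 1 before learning ends is
acceptable.

**NEF (batch least squares over tuning curves).** Encoders are unit
vectors; per-neuron gains and biases are solved so the closed-form LIF
rate is zero at a uniform random intercept in [-1, 1) and hits a maximum
rate drawn from 80-120 Hz at `x = 1` along the preferred direction
(`tau_m` 20 ms, `t_ref` 2 ms, `tau_syn` 10 ms, dt 1 ms). Expected
activities at 2000 uniform evaluation points in the latent box feed a
ridge-regularized least-squares solve for `Phi` (regularizer
`(0.01 * max activity)^2 * M`; 0.01 keeps decoder shrinkage — which acts
as a leak on the attractor — below 0.1%). Activities are in Hz; the
spiking readout divides the filtered traces by `tau_syn` accordingly.

**Efficient coding (analytically fixed weights).** No learning:
`Phi = lambda K'` with `lambda = 1/tau_syn`, slow weights
`lambda K K'`, instantaneous fast weights `-K K' - mu lambda^2 I` whose
inhibitory autapses implement the reset, and per-neuron thresholds
`(nu lambda + mu lambda^2 + ||k_j||^2) / 2` (`tau_m` 50 ms, `tau_syn`
20 ms, `nu = 1e-3`, `mu = 1e-6`). The printed formulas of this network
family mix two decoder conventions; the only self-consistent pairing with
the stated per-spike voltage decrement `||k_j||^2 + mu lambda^2` is the
estimate `x_hat = K' u` (each spike of neuron j moves the estimate by
`k_j`), with currents interpreted in voltage-rate units
(`dV/dt = -V/tau_m + I`). The simulator uses that pairing; latent targets
are scaled x100 internally and scaled back for reporting.

Because the encoder row norm is not pinned down by the framework, it is a
regime choice: with unit rows the per-spike reset `||k||^2` dwarfs the
quadratic rate cost `mu lambda^2` and the greedy spike rule concentrates
all spikes on the few best-aligned neurons (a sparse-coding regime,
~3 Hz mean rate, whose count patterns align poorly with `K`). The package
default row norm 0.05 makes the two costs equal, which spreads spikes
across the aligned population (load sharing), yields cortex-range rates
(~50 Hz) and broad cosine-like tuning. This choice is fixed once and used
everywhere.

## Latent dynamics

Feeding back `Gamma u` with `Gamma = (tau_syn A + I) Phi` makes the
latents evolve as `dx/dt = A x`; `A = 0` recovers the integrator and the
antisymmetric `A = [[0, -w], [w, 0]]` a planar oscillator at `f = w/2pi`.
For nonlinear dynamics `dx/dt = f(x)` the feedback target generalizes to
`tau_syn f(x) + x`. The 4-D field used by the Daleian network couples a
2 Hz and a 4 Hz rotation pair with a radial term `alpha (1 - r^2) x`
(`alpha = 0.2`) that makes unit-amplitude cycles attracting; from small
amplitudes the cycle grows at rate `alpha`, so closed-loop simulations
run 20 s and discard the first 60% as transient.

## Sign-constrained Daleian weights

To obtain a biologically plausible `W` directly, the optimization is
moved from decoders to weights: each postsynaptic row of `W` minimizes
the squared error against its target current
`gain_j * k_j . (tau f(x) + x)` over the evaluation set, subject to a
random sign mask `C` — entries forbidden with probability `xi = 0.75`,
otherwise positive for the first 80% of presynaptic columns and negative
for the rest (`eps_frac = 0.8`). Each row is a non-negative least-squares
problem after negating inhibitory columns and dropping masked ones; the
rows share one gram matrix, solved by an active-set method on the gram
form. The result is sparse, Daleian, E/I balanced, has rank above D, and
heavy-tailed weights — and it still pays a much smaller rewiring cost for
inside than for outside permutations.

## Similarity measures

* `subspace_cosine(A, B)`: cosine of the mean principal angle between the
  column spaces (singular values of the cross-product of orthonormalized
  bases, clipped to [0, 1] before `acos`); 1 = same space, 0 = orthogonal.
  Invariant to any invertible recombination, so blind to within-manifold
  permutations.
* `columnwise_similarity`: mean absolute Pearson correlation of matched
  columns; detects within-manifold permutations.
* `weight_similarity`: element-wise Pearson correlation over all N^2
  entries of the feedback component `W` only (the static reservoir and
  the EC fast weights are excluded), plus the Frobenius norm of the
  difference, which unlike the correlation is sensitive to global
  rescaling.
* `pca_modes` / `fa_modes`: neural modes from 50 ms binned counts. PCA
  centers per neuron without variance scaling (counts share units).
  Factor analysis is fitted by EM on the sample covariance with per-neuron
  noise floors — `stats::factanal` cannot handle 1000 neurons with 50
  bins — converged at 1e-3 on the log-likelihood, max 1000 iterations.

## Numerical choices

* Membrane integration is exponential-Euler (exact for the linear part)
  with sub-step spike-time interpolation and continuous refractory
  bookkeeping. The interpolation matters: with a plain per-step threshold
  test at dt = 1 ms, steady-state rates run ~8% below the closed-form f-I
  curve used for calibration, which closed-loop acts as an ~8/s leak and,
  e.g., collapses the Daleian limit cycle (growth rate 0.2/s).
* EC fast synapses are same-step voltage jumps; within a step the
  largest-overshoot neuron spikes first and its fast weights are applied
  before re-testing, which keeps spiking asynchronous. A runaway guard
  aborts if a step needs 500+ spikes.
* The FORCE loop updates `P` before `Phi` (the decoder update uses the
  updated `P`), matching the printed update order.
* Reservoir row balancing subtracts the row mean from the nonzero entries
  (keeping sparsity); a dense variant is available.
* NNLS tolerance: masked entries are exactly zero by construction; active
  set iterations are capped at 500 per row with per-row convergence
  reporting. Connection probabilities count entries with
  `|w| > 1e-9 max|w|`.
* Zero-crossing frequency estimates smooth with a 25 ms boxcar first.

## Scale profiles

`study_config("desk")` targets a single CPU: NEF and EC at the study's
native N = 1000; FORCE at N = 300 (20 s training at dt = 0.05 ms for the
single-network study; 10 s at dt = 0.1 ms for the 5-instantiation
perturbation study); the Daleian network at N = 500 with 4000 evaluation
points. `study_config("full")` restores N = 1000 FORCE with 45 s
training, 30 instantiations, and the N = 5000 / 40000-evaluation-point
Daleian solve (hours of compute). The printed full-scale Daleian numbers
(connection probabilities 10.8% / 19.0%, log-weight kurtosis 4.56) are
full-profile quantities; the desk profile reproduces the qualitative
structure (Dale compliance, rank > D, E/I balance, inside > outside) but
its connection probabilities are smaller (~8% / ~17% at N = 500).

## What the generator emulates, and what it does not

All inputs are synthetic by design: random encoders, step-hold fixation
schedules (values re-drawn uniformly in [-1, 1] every 500 ms, clamped for
100 ms), harmonic and limit-cycle reference trajectories, and random sign
masks. They emulate the *study's* conditions, not recorded data: real
populations have heterogeneous cell types, correlated noise, >10-D
manifolds and partial observation. Passing tests therefore show that the
connectivity-manifold relationship behaves as derived under these
idealized conditions, not that the quantitative values transfer to
cortex.

## Known limitations

* The NEF integrator drifts between fixations (the decode-error vector
  field, ~0.4 RMS over 400 ms windows at N = 1000); this mirrors the
  reference behavior of such attractors but means retention is
  qualitative, not exact.
* The principal-angle alignment between encoders and empirical PCA modes
  runs at 0.78-0.85 for the NEF configuration here, somewhat above the
  ~0.7 reported for the original simulator stack; per-instantiation
  spread is large (sd ~0.1) because only 50 bins enter the PCA.
* FORCE relearning quality depends on training length; the desk profile
  is tuned for the weight-correlation comparisons, not for minimal
  decoding error.
* Only LIF neurons and single exponential synapses are implemented; no
  conductance synapses, heterogeneous time constants, or online NEF/EC
  learning rules.
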