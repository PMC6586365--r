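// Core simulation loops: leaky integrate-and-fire networks under the three
// construction frameworks, plus the gram-based NNLS used by the Daleian
// solver. Kept in C++ because the desk-scale studies run 1e5-1e6 time steps
// on a single CPU.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Exponential-Euler membrane update: exact for the linear part given a
// current held constant over the step.
static inline void membrane_step(arma::vec& V, const arma::vec& I,
                                 double vleak, double rm,
                                 double decay_m) {
  // V <- target + (V - target) * exp(-dt/tau_m), target = vleak + rm*I
  arma::uword n = V.n_elem;
  for (arma::uword j = 0; j < n; ++j) {
    double tgt = vleak + rm * I[j];
    V[j] = tgt + (V[j] - tgt) * decay_m;
  }
}

// Generic LIF network. Current to neuron j at step t:
//   I_j = Iext(j,t) + bias(j) + (Wdense * u_sc)_j + (Kg * x_fb)_j
// where x_fb = x_clamp(,t) when clamp(t) != 0, else Dec * u_sc, and
// u_sc = u / tau_syn when u_in_hz (filtered traces read out in Hz).
// [[Rcpp::export]]
List cpp_lif_sim(const arma::mat& Iext,      // N x T or 0 x 0
                 const arma::vec& bias,      // N
                 const arma::mat& Wdense,    // N x N or 0 x 0
                 const arma::mat& Kg,        // N x D or 0 x 0 (gain-scaled)
                 const arma::mat& Dec,       // D x N feedback decoder
                 const arma::mat& x_clamp,   // D x T or 0 x 0
                 const arma::ivec& clamp,    // T (0/1), or length 0
                 int n, int nt,
                 double dt, double tau_m, double tau_syn,
                 double rm, double vleak, const arma::vec& vth,
                 double vreset, double t_ref,
                 const arma::vec& v0,
                 bool u_in_hz, int record_stride) {
  arma::vec V = v0;
  arma::vec u(n, arma::fill::zeros);
  arma::vec refr_left(n, arma::fill::zeros);   // seconds of refractory left
  const double decay_m = std::exp(-dt / tau_m);
  const double decay_s = std::exp(-dt / tau_syn);
  const bool has_ext = Iext.n_elem > 0;
  const bool has_dense = Wdense.n_elem > 0;
  const bool has_fb = Kg.n_elem > 0;
  const int d = has_fb ? (int)Kg.n_cols : 0;
  const double usc_fac = u_in_hz ? 1.0 / tau_syn : 1.0;

  std::vector<int> sp_id;
  std::vector<double> sp_t;
  int nrec = (record_stride > 0) ? nt / record_stride : 0;
  arma::mat xrec(d > 0 ? d : 1, nrec > 0 ? nrec : 1, arma::fill::zeros);
  int irec = 0;

  arma::vec I(n), usc(n), xfb(d > 0 ? d : 1);
  for (int t = 0; t < nt; ++t) {
    usc = u * usc_fac;
    I = bias;
    if (has_ext) I += Iext.col(t);
    if (has_dense) I += Wdense * usc;
    if (has_fb) {
      if (clamp.n_elem > 0 && clamp[t] != 0) xfb = x_clamp.col(t);
      else xfb = Dec * usc;
      I += Kg * xfb;
    }
    if (!I.is_finite())
      stop("non-finite input current at step %d", t + 1);
    // membrane update with continuous refractory bookkeeping and sub-step
    // spike-time interpolation (keeps steady-state rates at the closed-form
    // f-I curve even at coarse dt)
    u *= decay_s;
    for (int j = 0; j < n; ++j) {
      double free_t = dt - refr_left[j];
      if (free_t <= 0.0) {            // fully refractory this step
        refr_left[j] -= dt;
        V[j] = vreset;
        continue;
      }
      double vstart = (refr_left[j] > 0.0) ? vreset : V[j];
      refr_left[j] = 0.0;
      double tgt = vleak + rm * I[j];
      double dec = (free_t == dt) ? decay_m : std::exp(-free_t / tau_m);
      double vnew = tgt + (vstart - tgt) * dec;
      if (vnew >= vth[j]) {
        // linear interpolation of the crossing within the free window
        double denom = vnew - vstart;
        double after = (denom > 0.0) ? (vnew - vth[j]) / denom * free_t : 0.0;
        sp_id.push_back(j + 1);
        sp_t.push_back((t + 1) * dt - after);
        V[j] = vreset;
        refr_left[j] = std::max(0.0, t_ref - after);
        u[j] += 1.0;
      } else {
        V[j] = vnew;
      }
    }
    if (record_stride > 0 && (t + 1) % record_stride == 0) {
      if (has_fb) xrec.col(irec) = Dec * (u * usc_fac);
      irec++;
    }
  }
  return List::create(_["spike_id"] = sp_id, _["spike_time"] = sp_t,
                      _["x_rec"] = xrec, _["u_final"] = u,
                      _["v_final"] = V);
}

// FORCE training: reservoir current Omega*u plus feedback K*x_fb with
//   x_fb = x_target during clamp, else ramp*x_dec + (1-ramp)*x_target,
// and recursive-least-squares updates of (P, Phi) every `stride` steps
// while learn(t) != 0. P is updated first; Phi uses the updated P.
// [[Rcpp::export]]
List cpp_force_train(const arma::mat& Omega,    // N x N
                     const arma::mat& K,        // N x D
                     const arma::mat& x_target, // D x T
                     const arma::vec& ramp,     // T in [0,1]
                     const arma::ivec& clamp,   // T 0/1
                     const arma::ivec& learn,   // T 0/1
                     int stride, double p0,
                     arma::mat Phi,             // D x N initial (usually 0)
                     double dt, double tau_m, double tau_syn,
                     double rm, double vleak, double vth,
                     double vreset, double t_ref,
                     const arma::vec& v0, int record_stride) {
  const int n = Omega.n_rows, d = K.n_cols, nt = x_target.n_cols;
  arma::vec V = v0;
  arma::vec u(n, arma::fill::zeros);
  arma::ivec refr(n, arma::fill::zeros);
  arma::mat P(n, n, arma::fill::eye);
  P *= p0;
  const double decay_m = std::exp(-dt / tau_m);
  const double decay_s = std::exp(-dt / tau_syn);
  const int ref_steps = (t_ref > 0) ? (int)std::lround(t_ref / dt) : 0;
  arma::vec vthv(n); vthv.fill(vth);

  std::vector<int> sp_id;
  std::vector<double> sp_t;
  int nrec = (record_stride > 0) ? nt / record_stride : 0;
  arma::mat xrec(d, nrec > 0 ? nrec : 1, arma::fill::zeros);
  int irec = 0;
  int silent_steps = 0, max_silent = 0;

  arma::vec I(n), xdec(d), xfb(d), Pu(n), e(d);
  for (int t = 0; t < nt; ++t) {
    xdec = Phi * u;
    if (clamp[t] != 0) xfb = x_target.col(t);
    else xfb = ramp[t] * xdec + (1.0 - ramp[t]) * x_target.col(t);
    I = Omega * u + K * xfb;
    if (!I.is_finite())
      stop("non-finite input current at step %d", t + 1);
    membrane_step(V, I, vleak, rm, decay_m);
    for (int j = 0; j < n; ++j)
      if (refr[j] > 0) { V[j] = vreset; refr[j]--; }
    u *= decay_s;
    int nsp = 0;
    for (int j = 0; j < n; ++j) {
      if (refr[j] == 0 && V[j] >= vthv[j]) {
        sp_id.push_back(j + 1);
        sp_t.push_back((t + 1) * dt);
        V[j] = vreset;
        refr[j] = ref_steps;
        u[j] += 1.0;
        nsp++;
      }
    }
    if (nsp == 0) { silent_steps++; if (silent_steps > max_silent) max_silent = silent_steps; }
    else silent_steps = 0;
    if (learn[t] != 0 && (t + 1) % stride == 0) {
      Pu = P * u;
      double den = 1.0 + arma::dot(u, Pu);
      P -= (Pu * Pu.t()) / den;
      Pu = P * u;                         // P(t) u for the decoder update
      e = (Phi * u) - x_target.col(t);
      Phi -= e * Pu.t();
    }
    if (record_stride > 0 && (t + 1) % record_stride == 0) {
      xrec.col(irec) = Phi * u;
      irec++;
    }
  }
  return List::create(_["Phi"] = Phi, _["spike_id"] = sp_id,
                      _["spike_time"] = sp_t, _["x_rec"] = xrec,
                      _["max_silent_steps"] = max_silent,
                      _["P_final"] = P);
}

// Efficient-coding network: slow current K * (Gslow * u) (replaced by
// K * x_clamp during fixation), fast synapses applied as same-step voltage
// jumps by the columns of Omega_f (inhibitory autapses on the diagonal act
// as the reset). One spike at a time within a step, largest overshoot
// first, fast weights applied before re-testing. Currents are in
// voltage-rate units (dV/dt = -V/tau_m + I), the convention under which
// the slow drive lambda*K*K'u balances the per-spike decoder increments;
// the decoded estimate is x_hat = K'u.
// [[Rcpp::export]]
List cpp_ec_sim(const arma::mat& K,         // N x D
                const arma::mat& Gslow,     // D x N (= lambda*(tau*A + I)*K^T)
                const arma::mat& Omega_f,   // N x N fast weights
                const arma::vec& vth,       // N
                const arma::mat& x_clamp,   // D x T
                const arma::ivec& clamp,    // T
                double dt, double tau_m, double tau_syn,
                const arma::vec& v0, const arma::vec& noise_step_sd,
                int record_stride, int max_spikes_per_step) {
  const int n = K.n_rows, d = K.n_cols, nt = clamp.n_elem;
  arma::vec V = v0;
  arma::vec u(n, arma::fill::zeros);
  const double decay_m = std::exp(-dt / tau_m);
  const double decay_s = std::exp(-dt / tau_syn);

  std::vector<int> sp_id;
  std::vector<double> sp_t;
  int nrec = (record_stride > 0) ? nt / record_stride : 0;
  arma::mat xrec(d, nrec > 0 ? nrec : 1, arma::fill::zeros);
  int irec = 0;

  arma::vec I(n), xfb(d);
  for (int t = 0; t < nt; ++t) {
    if (clamp[t] != 0) xfb = x_clamp.col(t);
    else xfb = Gslow * u;
    I = K * xfb;
    if (!I.is_finite())
      stop("non-finite input current at step %d", t + 1);
    // dV/dt = -V/tau_m + I  =>  equilibrium tau_m * I
    membrane_step(V, I, 0.0, tau_m, decay_m);
    if (noise_step_sd.n_elem > 0)
      for (int j = 0; j < n; ++j)
        V[j] += noise_step_sd[j] * norm_rand();
    u *= decay_s;
    int nsp = 0;
    while (nsp < max_spikes_per_step) {
      arma::vec over = V - vth;
      arma::uword jmax = over.index_max();
      if (over[jmax] < 0) break;
      sp_id.push_back((int)jmax + 1);
      sp_t.push_back((t + 1) * dt);
      V += Omega_f.col(jmax);             // instantaneous fast synapses
      u[jmax] += 1.0;
      nsp++;
    }
    if (nsp >= max_spikes_per_step)
      stop("runaway spiking at step %d: >= %d spikes in one step; "
           "increase mu or reduce dt", t + 1, max_spikes_per_step);
    if (record_stride > 0 && (t + 1) % record_stride == 0) {
      xrec.col(irec) = K.t() * u;     // decoded estimate (per-spike unit k_j)
      irec++;
    }
  }
  return List::create(_["spike_id"] = sp_id, _["spike_time"] = sp_t,
                      _["x_rec"] = xrec, _["u_final"] = u,
                      _["v_final"] = V);
}

// Lawson-Hanson NNLS working on the gram matrix G = A'A and f = A'b.
static arma::vec nnls_gram(const arma::mat& G, const arma::vec& f,
                           int max_iter, bool& ok) {
  const int p = G.n_rows;
  arma::vec x(p, arma::fill::zeros);
  std::vector<bool> passive(p, false);
  arma::vec w = f;                      // gradient -0.5 d/dx ||b - Ax||^2
  const double tol = 1e-10 * (1.0 + arma::abs(f).max());
  int it = 0;
  ok = true;
  while (it++ < max_iter) {
    // pick the most promising free variable
    int jbest = -1; double wbest = tol;
    for (int j = 0; j < p; ++j)
      if (!passive[j] && w[j] > wbest) { wbest = w[j]; jbest = j; }
    if (jbest < 0) break;
    passive[jbest] = true;
    // inner loop: solve on the passive set, step back if infeasible
    for (;;) {
      arma::uvec P(p); int np = 0;
      for (int j = 0; j < p; ++j) if (passive[j]) P[np++] = j;
      P.resize(np);
      arma::vec z;
      bool solved = arma::solve(z, G.submat(P, P), f.elem(P),
                                arma::solve_opts::likely_sympd);
      if (!solved) { ok = false; return x; }
      if (z.min() > 0) {
        x.zeros();
        x.elem(P) = z;
        break;
      }
      double alpha = 1.0;
      for (int i = 0; i < np; ++i)
        if (z[i] <= 0) {
          double a = x[P[i]] / (x[P[i]] - z[i]);
          if (a < alpha) alpha = a;
        }
      for (int i = 0; i < np; ++i)
        x[P[i]] += alpha * (z[i] - x[P[i]]);
      for (int i = 0; i < np; ++i)
        if (x[P[i]] <= 1e-14) { passive[P[i]] = false; x[P[i]] = 0.0; }
    }
    w = f - G * x;
  }
  if (it >= max_iter) ok = false;
  return x;
}

// Row-wise sign-constrained least squares: for each postsynaptic neuron j,
//   min || Y(,j) - U * w_j ||^2  s.t. sign(w_j(i)) in {0, C(j,i)},
// solved as NNLS after negating inhibitory columns and dropping masked ones.
// [[Rcpp::export]]
List cpp_solve_constrained(const arma::mat& U,   // M x N activities
                           const arma::mat& Y,   // M x N targets (col j)
                           const arma::imat& C,  // N x N sign mask (row j)
                           int max_iter) {
  const int n = U.n_cols;
  arma::mat G = U.t() * U;            // shared gram across rows
  arma::mat F = U.t() * Y;            // F(,j) = U' y_j
  arma::vec ynorm2 = arma::sum(arma::square(Y), 0).t();
  arma::mat W(n, n, arma::fill::zeros);
  arma::vec resid(n, arma::fill::zeros);
  arma::ivec conv(n, arma::fill::ones);
  for (int j = 0; j < n; ++j) {
    arma::uvec idx = arma::find(C.row(j).t() != 0);
    if (idx.n_elem == 0) { resid[j] = ynorm2[j]; continue; }
    arma::vec s(idx.n_elem);
    for (arma::uword i = 0; i < idx.n_elem; ++i)
      s[i] = (double)C(j, idx[i]);
    arma::mat Gs = G.submat(idx, idx) % (s * s.t());
    arma::vec fcol = F.col(j);
    arma::vec fs = s % fcol.elem(idx);
    bool ok = true;
    arma::vec x = nnls_gram(Gs, fs, max_iter, ok);
    if (!ok) conv[j] = 0;
    arma::vec wrow = s % x;
    for (arma::uword i = 0; i < idx.n_elem; ++i)
      W(j, idx[i]) = wrow[i];
    resid[j] = ynorm2[j] - 2.0 * arma::dot(x, fs) +
               arma::dot(x, Gs * x);
  }
  return List::create(_["W"] = W, _["residuals"] = resid,
                      _["converged"] = conv);
}

// Single NNLS solve on gram form, exposed for testing against independent
// oracles (pracma::lsqnonneg, brute-force active sets).
// [[Rcpp::export]]
arma::vec cpp_nnls_gram(const arma::mat& G, const arma::vec& f,
                        int max_iter) {
  bool ok = true;
  arma::vec x = nnls_gram(G, f, max_iter, ok);
  if (!ok) stop("NNLS did not converge");
  return x;
}
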