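#' Desk-scale study configuration
#'
#' Bundles the sizes and seeds the orchestration functions use. The
#' `desk` profile targets a single CPU: the rate-based frameworks run at
#' the study's native N = 1000 while the spiking FORCE runs at N = 300
#' with shortened training; the Daleian network runs at N = 500 with
#' 4000 evaluation points. The `full` profile restores the study's
#' printed sizes (N = 1000 FORCE with 45 s training; N = 5000, 40000
#' evaluation points for the Daleian network) and is hours of compute.
#'
#' @param profile `"desk"` or `"full"`
#' @param seed master integer seed
#' @return a named list of settings
#' @export
study_config <- function(profile = c("desk", "full"), seed = 1) {
  profile <- match.arg(profile)
  desk <- list(
    profile = profile, seed = seed,
    n_nef = 1000, n_ec = 1000, n_force = 300,
    d = 2, n_eval = 2000,
    force_learn_s = 20, force_free_s = 2.5, force_dt = 5e-5,
    force_relearn_learn_s = 10, force_relearn_dt = 1e-4,
    ec_dt = 1e-4, nef_dt = 1e-3,
    n_rep = 5,
    ec_encoder_norm = 0.05,
    dale_n = 500, dale_n_eval = 4000,
    freqs_hz = seq(0, 16, by = 2))
  if (profile == "full") {
    desk$n_force <- 1000
    desk$force_learn_s <- 45; desk$force_free_s <- 5
    desk$force_relearn_learn_s <- 45; desk$force_relearn_dt <- 5e-5
    desk$n_rep <- 30
    desk$dale_n <- 5000; desk$dale_n_eval <- 40000
  }
  desk
}

fixation_protocol <- function(d, dt, duration = 2.5, seed = NULL) {
  make_step_targets(d, duration = duration, dt = dt, period = 0.5,
                    fix_len = 0.1, seed = seed)
}

build_and_run_framework <- function(framework, config, seed) {
  d <- config$d
  if (framework == "force") {
    withr::local_seed(seed)
    K <- draw_encoders("uniform_box", config$n_force, d, scale = 100)
    Omega <- build_reservoir(config$n_force, 0.1, G = 10)
    target <- fixation_protocol(d, config$force_dt)
    sched <- training_schedule(target, learn_s = config$force_learn_s,
                               free_s = config$force_free_s)
    net <- force_train(K, Omega, sched, dt = config$force_dt)
    # evaluation window: the final free-running cycle
    total <- config$force_learn_s + config$force_free_s
    win <- c(total - 2.5, total)
    raster <- net$raster |>
      dplyr::filter(.data$time > win[1], .data$time <= win[2]) |>
      dplyr::mutate(time = .data$time - win[1])
    raster <- new_spike_raster(raster$neuron, raster$time,
                               config$n_force, 2.5)
    list(net = net, raster = raster,
         K = unclass(net$K), PhiT = t(net$Phi))
  } else if (framework == "nef") {
    net <- build_nef_network(config$n_nef, d, config$n_eval, seed = seed)
    target <- fixation_protocol(d, config$nef_dt, seed = seed + 1000L)
    sim <- simulate_nef(net, target, dt = config$nef_dt)
    list(net = net, raster = sim$raster, x_dec = sim$x_dec,
         K = unclass(net$K), PhiT = t(net$Phi))
  } else if (framework == "ec") {
    withr::local_seed(seed)
    K <- config$ec_encoder_norm *
      unclass(draw_encoders("unit_sphere_rows", config$n_ec, d))
    net <- build_ec_network(K)
    target <- fixation_protocol(d, config$ec_dt, seed = seed + 1000L)
    sim <- simulate_ec(net, target, dt = config$ec_dt)
    list(net = net, raster = sim$raster, x_dec = sim$x_dec,
         K = unclass(net$K), PhiT = t(net$Phi))
  } else stop("unknown framework: ", framework)
}

#' Manifold-similarity study: encoders determine modes and decoders
#'
#' For each framework, builds the D = 2 network, runs the periodic
#' latent-fixation protocol, bins spikes in 50 ms windows, extracts PCA
#' and factor-analysis neural modes and computes the generalized
#' correlation (cosine of mean principal angles) between every pair of
#' `K`, `Phi'`, `Z_PCA`, `Z_FA`.
#'
#' @param config a [study_config()] list
#' @param frameworks character subset of `c("force", "nef", "ec")`
#' @return a list with tibbles `similarity` (framework, a, b, cosine) and
#'   `variance` (framework, component, fraction), plus `runs` (per
#'   framework: net, raster, modes)
#' @export
run_manifold_similarity <- function(config = study_config(),
                                    frameworks = c("force", "nef", "ec")) {
  runs <- purrr::map(frameworks, function(fw) {
    run <- build_and_run_framework(fw, config, config$seed)
    rates <- bin_spikes(run$raster, 0.05)
    zpca <- pca_modes(rates, config$d)
    zfa <- fa_modes(rates, config$d)
    sim <- subspace_similarity_table(K = run$K, PhiT = run$PhiT,
                                     Z_PCA = zpca, Z_FA = zfa) |>
      dplyr::mutate(framework = fw, .before = 1)
    list(framework = fw, net = run$net, raster = run$raster,
         rates = rates, Z_PCA = zpca, Z_FA = zfa, similarity = sim)
  })
  names(runs) <- frameworks
  list(similarity = purrr::map_dfr(runs, "similarity"),
       variance = purrr::map_dfr(runs, function(r)
         tibble::tibble(framework = r$framework,
                        component = seq_along(attr(r$Z_PCA, "variance_explained")),
                        fraction = attr(r$Z_PCA, "variance_explained"))),
       runs = runs)
}

force_relearn_config <- function(config) {
  cfg <- config
  cfg$force_learn_s <- config$force_relearn_learn_s
  cfg$force_dt <- config$force_relearn_dt
  cfg
}

#' Perturbation study: weight changes required inside vs outside
#'
#' For each instantiation and framework: build the network, apply every
#' perturbation condition, relearn with identical hyperparameters, and
#' record the element-wise Pearson correlation and Frobenius difference
#' between the old and new feedback weight matrices.
#'
#' @param config a [study_config()] list
#' @param frameworks subset of `c("force", "nef", "ec")`
#' @param kinds perturbation conditions (see [perturb_and_relearn()])
#' @return a tibble (framework, kind, rep, pearson, frobenius)
#' @export
run_perturbation_study <- function(config = study_config(),
                                   frameworks = c("force", "nef", "ec"),
                                   kinds = c("identity",
                                             "inside_permutation",
                                             "inside_rot45",
                                             "inside_gaussian",
                                             "inside_same_element",
                                             "outside_block_swap",
                                             "redraw_K")) {
  cfg <- force_relearn_config(config)
  purrr::map_dfr(frameworks, function(fw) {
    purrr::map_dfr(seq_len(config$n_rep), function(rep) {
      base_seed <- config$seed + 97L * rep
      base <- build_base_network(fw, cfg, base_seed)
      purrr::map_dfr(seq_along(kinds), function(ki) {
        pert <- perturb_and_relearn(base, kinds[ki],
                                    seed = base_seed + 1000L * ki)
        weight_similarity(pert$W_old, pert$W_new) |>
          dplyr::mutate(framework = fw, kind = kinds[ki], rep = rep,
                        .before = 1)
      })
    })
  })
}

build_base_network <- function(framework, config, seed, A = NULL) {
  d <- config$d
  if (framework == "force") {
    withr::local_seed(seed)
    K <- draw_encoders("uniform_box", config$n_force, d, scale = 100)
    Omega <- build_reservoir(config$n_force, 0.1, G = 10)
    target <- fixation_protocol(d, config$force_dt)
    sched <- training_schedule(target, learn_s = config$force_learn_s,
                               free_s = 0)
    force_train(K, Omega, sched, dt = config$force_dt)
  } else if (framework == "nef") {
    build_nef_network(config$n_nef, d, config$n_eval, A = A, seed = seed)
  } else {
    withr::local_seed(seed)
    K <- config$ec_encoder_norm *
      unclass(draw_encoders("unit_sphere_rows", config$n_ec, d))
    net <- build_ec_network(K)
    if (!is.null(A)) net <- ec_dynamics_weights(net, A)
    net
  }
}

#' Oscillator-frequency scan: decoders drift from encoders with speed
#'
#' Builds, per framework and oscillation frequency, a network whose two
#' latent variables rotate at `f` Hz, and measures the element-wise
#' correlation between `K` and the feedback decoders `Gamma'` (plus the
#' Efficient Coding analytic value `(tau_syn A + I)` applied to `Phi`).
#' Optionally also measures inside/outside perturbation weight
#' correlations at each frequency.
#'
#' @param config a [study_config()] list
#' @param frameworks subset of `c("force", "nef", "ec")` (FORCE retrains
#'   per frequency and is the slow one)
#' @param with_perturbations also relearn under an inside permutation and
#'   an outside block swap at each frequency
#' @return a tibble (framework, f_hz, corr_K_Gamma, corr_K_Phi,
#'   corr_analytic, and optionally pearson_inside / pearson_outside)
#' @export
run_oscillator_scan <- function(config = study_config(),
                                frameworks = c("nef", "ec"),
                                with_perturbations = FALSE) {
  cfg <- force_relearn_config(config)
  purrr::map_dfr(frameworks, function(fw) {
    purrr::map_dfr(config$freqs_hz, function(f) {
      A <- oscillator_A(f)
      # one network instantiation per framework: the frequency curve is
      # not confounded by re-draws of K / tuning
      seed <- config$seed
      net <- build_osc_network(fw, cfg, seed, f)
      K <- unclass(net$K)
      Gamma <- net$Gamma
      Phi <- net$Phi
      analytic <- dynamics_transform(A, Phi, net$tau_syn)
      out <- tibble::tibble(
        framework = fw, f_hz = f,
        corr_K_Gamma = stats::cor(as.numeric(K), as.numeric(t(Gamma))),
        corr_K_Phi = stats::cor(as.numeric(K), as.numeric(t(Phi))),
        corr_analytic = stats::cor(as.numeric(K), as.numeric(t(analytic))),
        gamma_analytic_maxdiff = max(abs(Gamma - analytic)))
      if (with_perturbations) {
        pin <- perturb_and_relearn(net, "inside_permutation",
                                   seed = seed + 7L)
        pout <- perturb_and_relearn(net, "outside_block_swap",
                                    seed = seed + 8L)
        out$pearson_inside <-
          weight_similarity(pin$W_old, pin$W_new)$pearson
        out$pearson_outside <-
          weight_similarity(pout$W_old, pout$W_new)$pearson
      }
      out
    })
  })
}

build_osc_network <- function(framework, config, seed, f_hz) {
  A <- oscillator_A(f_hz)
  if (framework == "force") {
    withr::local_seed(seed)
    K <- draw_encoders("uniform_box", config$n_force, 2, scale = 100)
    Omega <- build_reservoir(config$n_force, 0.1, G = 10)
    target <- make_oscillator_targets(f_hz, 2.5, config$force_dt)
    # seed the loop with brief clamps at each cycle start
    sched <- training_schedule(target, learn_s = config$force_learn_s,
                               free_s = 0)
    net <- force_train(K, Omega, sched, dt = config$force_dt)
    net$Gamma <- net$Phi
    net$tau_syn <- 0.02
    net
  } else if (framework == "nef") {
    build_nef_network(config$n_nef, 2, config$n_eval, A = A, seed = seed)
  } else {
    withr::local_seed(seed)
    K <- config$ec_encoder_norm *
      unclass(draw_encoders("unit_sphere_rows", config$n_ec, 2))
    ec_dynamics_weights(build_ec_network(K), A)
  }
}

#' Daleian network study: biologically constrained weights and their
#' perturbations
#'
#' Solves the sparse, Daleian N x N weight matrix for the 4-D nonlinear
#' oscillator, reports its weight statistics, correlates it against
#' relearned matrices for all 23 non-identity inside column permutations,
#' the 23 mirrored outside row-block permutations and (optionally) 23
#' redrawn encoder matrices, and simulates the closed loop decoding with
#' the unperturbed readout before and after one inside permutation.
#'
#' @param config a [study_config()] list
#' @param include_redraw also run the redrawn-encoder control
#' @param readout_perm the inside permutation used for the closed-loop
#'   readout comparison (default `c(3, 4, 1, 2)`: the 2 Hz and 4 Hz pairs
#'   exchange places)
#' @param sim_duration seconds of closed-loop simulation
#' @return a list: `net`, `stats`, `perturbations` (tibble), `readout`
#'   (decoded latent trajectories before/after), `freqs` (zero-crossing
#'   frequency estimates)
#' @export
run_daleian_study <- function(config = study_config(),
                              include_redraw = TRUE,
                              readout_perm = c(3, 4, 1, 2),
                              sim_duration = 20) {
  net <- build_dale_network(n = config$dale_n, d = 4,
                            n_eval = config$dale_n_eval,
                            seed = config$seed)
  stats <- weight_statistics(net$W, eps_frac = attr(net$mask, "eps_frac"))
  perms <- enumerate_inside_permutations(4)
  pert <- purrr::map_dfr(seq_along(perms), function(i) {
    p <- attr(perms[[i]], "perm")
    inside <- perturb_and_relearn(net, "inside_permutation",
                                  seed = config$seed + i, perm = p)
    outside <- perturb_and_relearn(net, "outside_block_permutation",
                                   seed = config$seed + 100L + i, perm = p)
    rows <- dplyr::bind_rows(
      weight_similarity(inside$W_old, inside$W_new) |>
        dplyr::mutate(condition = "inside", perm_id = i),
      weight_similarity(outside$W_old, outside$W_new) |>
        dplyr::mutate(condition = "outside", perm_id = i))
    if (include_redraw) {
      redraw <- perturb_and_relearn(net, "redraw_K",
                                    seed = config$seed + 200L + i)
      rows <- dplyr::bind_rows(rows,
        weight_similarity(redraw$W_old, redraw$W_new) |>
          dplyr::mutate(condition = "redraw", perm_id = i))
    }
    dplyr::mutate(rows, perm = paste(p, collapse = " "), .before = 1)
  })
  base_sim <- simulate_dale(net, duration = sim_duration,
                            seed = config$seed + 999L)
  pick <- which(vapply(perms, function(q)
    all(attr(q, "perm") == readout_perm), logical(1)))
  pert_net <- perturb_and_relearn(net, "inside_permutation",
                                  seed = config$seed + pick,
                                  perm = readout_perm)
  pert_dec <- readout_with_old_decoders(pert_net, net$Phi,
                                        duration = sim_duration,
                                        seed = config$seed + 999L)
  dt <- diff(base_sim$x_dec$time[1:2])
  disc <- 0.6 * sim_duration   # transient: the cycle grows from noise
  freqs <- tibble::tibble(
    latent = rep(1:4, 2),
    network = rep(c("original", "perturbed"), each = 4),
    f_hz = c(vapply(1:4, function(i)
      freq_zero_crossings(traj_matrix(base_sim$x_dec)[i, ], dt, disc), 0),
      vapply(1:4, function(i)
        freq_zero_crossings(traj_matrix(pert_dec)[i, ], dt, disc), 0)))
  list(net = net, stats = stats, perturbations = pert,
       readout = list(original = base_sim$x_dec, perturbed = pert_dec),
       readout_perm = readout_perm, freqs = freqs)
}
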