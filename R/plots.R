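#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_tile geom_rect labs facet_wrap scale_fill_gradient theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot decoded / target latent trajectories
#'
#' Lines per latent variable with fixation windows shaded.
#'
#' @param object a latent trajectory tibble
#' @param ... unused
#' @export
autoplot.latent_traj <- function(object, ...) {
  d <- traj_dims(object)
  long <- tidyr::pivot_longer(as.data.frame(object),
                              cols = dplyr::all_of(paste0("x", seq_len(d))),
                              names_to = "latent", values_to = "value")
  p <- ggplot(long, aes(x = .data$time, y = .data$value,
                        colour = .data$latent)) +
    geom_line() +
    labs(x = "time (s)", y = "latent value", colour = NULL) +
    theme_minimal()
  if (any(object$fixed)) {
    fx <- object$fixed
    starts <- object$time[which(fx & !dplyr::lag(fx, default = FALSE))]
    ends <- object$time[which(fx & !dplyr::lead(fx, default = FALSE))]
    shade <- data.frame(xmin = starts, xmax = ends)
    p <- p + geom_rect(data = shade,
                       aes(xmin = .data$xmin, xmax = .data$xmax,
                           ymin = -Inf, ymax = Inf),
                       inherit.aes = FALSE, alpha = 0.15, fill = "steelblue")
  }
  p
}

#' Spike raster plot
#' @param object a spike raster tibble
#' @param max_neurons show at most this many neurons (lowest ids)
#' @param ... unused
#' @export
autoplot.spike_raster <- function(object, max_neurons = 100, ...) {
  df <- dplyr::filter(object, .data$neuron <= max_neurons)
  ggplot(df, aes(x = .data$time, y = .data$neuron)) +
    geom_point(shape = ".", alpha = 0.6) +
    labs(x = "time (s)", y = "neuron") +
    theme_minimal()
}

#' Variance-explained spectrum of the neural modes
#' @param modes a `mode_matrix` from [pca_modes()], or the `variance`
#'   tibble from [run_manifold_similarity()]
#' @param n_components components to show
#' @export
plot_variance_spectrum <- function(modes, n_components = 10) {
  if (inherits(modes, "mode_matrix")) {
    ve <- attr(modes, "variance_explained")
    df <- data.frame(framework = "network",
                     component = seq_along(ve), fraction = ve)
  } else df <- as.data.frame(modes)
  df <- dplyr::filter(df, .data$component <= n_components)
  ggplot(df, aes(x = .data$component, y = .data$fraction)) +
    geom_col() +
    facet_wrap(~framework) +
    labs(x = "principal component", y = "fraction of variance") +
    theme_minimal()
}

#' Heatmap of pairwise subspace similarities
#' @param sim the `similarity` tibble from [run_manifold_similarity()]
#' @export
plot_similarity_matrix <- function(sim) {
  both <- dplyr::bind_rows(sim, dplyr::rename(sim, a = "b", b = "a"))
  ggplot(both, aes(x = .data$a, y = .data$b, fill = .data$cosine)) +
    geom_tile() +
    scale_fill_gradient(limits = c(0, 1), low = "white", high = "darkred") +
    facet_wrap(~framework) +
    labs(x = NULL, y = NULL, fill = "cos φ") +
    theme_minimal()
}

#' Weight-correlation summary across perturbation conditions
#' @param pert the tibble from [run_perturbation_study()]
#' @export
plot_perturbation_summary <- function(pert) {
  summ <- pert |>
    dplyr::group_by(.data$framework, .data$kind) |>
    dplyr::summarise(mean = mean(.data$pearson),
                     sd = stats::sd(.data$pearson), .groups = "drop")
  ggplot(summ, aes(x = .data$kind, y = .data$mean)) +
    geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(aes(ymin = .data$mean - .data$sd,
                               ymax = .data$mean + .data$sd), width = 0.3) +
    facet_wrap(~framework) +
    labs(x = NULL, y = "corr(W, W')") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
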