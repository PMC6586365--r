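#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a binned-rate matrix into long form
#'
#' @param x a `binned_rates` matrix
#' @param ... unused
#' @return a tibble (neuron, bin, time, count)
#' @export
tidy.binned_rates <- function(x, ...) {
  bw <- attr(x, "bin_width")
  m <- unclass(x)
  tibble::tibble(
    neuron = rep(seq_len(nrow(m)), times = ncol(m)),
    bin = rep(seq_len(ncol(m)), each = nrow(m)),
    time = (rep(seq_len(ncol(m)), each = nrow(m)) - 0.5) * bw,
    count = as.integer(m))
}

#' @export
tidy.mode_matrix <- function(x, ...) {
  m <- unclass(x)
  tibble::tibble(
    neuron = rep(seq_len(nrow(m)), times = ncol(m)),
    mode = rep(seq_len(ncol(m)), each = nrow(m)),
    loading = as.numeric(m))
}

#' @export
glance.dale_stats <- function(x, ...) {
  tibble::tibble(p_conn_exc = x$p_conn_exc, p_conn_inh = x$p_conn_inh,
                 ei_balance_cor = x$ei_balance_cor,
                 log_weight_kurtosis = x$log_weight_kurtosis,
                 log_weight_kurtosis_excess = x$log_weight_kurtosis_excess,
                 numerical_rank = x$numerical_rank, n = x$n)
}

#' @export
glance.manifold_net <- function(x, ...) {
  tibble::tibble(
    framework = class(x)[1],
    n = nrow(unclass(x$K)), d = ncol(unclass(x$K)),
    tau_syn = x$tau_syn %||% NA_real_,
    rank_W = qr(feedback_weights(x))$rank)
}

#' @export
tidy.perturbation_result <- function(x, ...) {
  weight_similarity(x$W_old, x$W_new) |>
    dplyr::mutate(kind = x$kind, .before = 1)
}

#' @export
print.manifold_net <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<%s> N = %d neurons, D = %d latent variables\n",
              g$framework, g$n, g$d))
  invisible(x)
}

#' @export
print.dale_stats <- function(x, ...) {
  cat(sprintf(paste0(
    "Daleian weight matrix (N = %d)\n",
    "  connection probability: %.1f%% (exc), %.1f%% (inh)\n",
    "  E/I balance correlation: %.3f\n",
    "  log-weight kurtosis: %.2f (excess %.2f)\n",
    "  numerical rank: %d\n"),
    x$n, 100 * x$p_conn_exc, 100 * x$p_conn_inh, x$ei_balance_cor,
    x$log_weight_kurtosis, x$log_weight_kurtosis_excess,
    x$numerical_rank))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
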