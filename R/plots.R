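#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the per-trial trace of the hierarchical filter
#'
#' @param x A `hafvf_trace` (see [hafvf_filter()]).
#' @param ... Unused.
#' @return A long tibble with columns `trial`, `quantity`, `value` for the
#'   main learning diagnostics.
#' @export
tidy.hafvf_trace <- function(x, ...) {
  tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(x), "trial", "mu", "kappa", "w_hat",
                  "b_hat", "eff_mem_w", "eff_mem_b", "elbo"),
    -"trial", names_to = "quantity", values_to = "value")
}

#' @rdname tidy.hafvf_trace
#' @export
glance.hafvf_trace <- function(x, ...) {
  tibble::tibble(n_trials = nrow(x), mean_elbo = mean(x$elbo),
                 final_w_hat = x$w_hat[nrow(x)],
                 final_b_hat = x$b_hat[nrow(x)],
                 final_kappa = x$kappa[nrow(x)],
                 final_eff_mem = x$eff_mem_w[nrow(x)])
}

#' Tidy a signal MAP fit
#'
#' @param x A `hafvf_map` (see [fit_signal_map()]).
#' @param ... Unused.
#' @return One row per parameter with unbounded and natural-scale values.
#' @export
tidy.hafvf_map <- function(x, ...) {
  u <- x$par_unbounded
  natural <- c(u[["mu0"]], softplus(u[["kappa0"]]), softplus(u[["alpha0"]]),
               softplus(u[["beta0"]]), softplus(u[["phi_a"]]),
               softplus(u[["phi_b"]]), softplus(u[["bet_a"]]),
               softplus(u[["bet_b"]]))
  tibble::tibble(term = names(u), unbounded = as.numeric(u),
                 estimate = natural)
}

#' @rdname tidy.hafvf_map
#' @export
glance.hafvf_map <- function(x, ...) {
  tibble::tibble(n_trials = x$n_trials, logjoint = x$logjoint,
                 evidence = if (is.null(x$evidence)) NA_real_ else
                   x$evidence,
                 convergence = x$convergence)
}

#' Tidy an actor MAP fit
#'
#' @param x A `hafvf_map_fit` (see [map_fit()]).
#' @param ... Unused.
#' @return Long tibble of per-subject diffusion parameter estimates.
#' @export
tidy.hafvf_map_fit <- function(x, ...) {
  tidyr::pivot_longer(x$subjects, -"subject", names_to = "term",
                      values_to = "estimate")
}

#' @rdname tidy.hafvf_map_fit
#' @export
glance.hafvf_map_fit <- function(x, ...) {
  tibble::tibble(n_subjects = nrow(x$subjects),
                 final_bound = x$final_bound,
                 n_iter = length(x$loss_trace))
}

#' Plot the learning trace of the hierarchical filter
#'
#' Three panels: observations with the posterior mean, the expected
#' forgetting factors at the two levels, and the effective versus efficient
#' memory.
#'
#' @param object A `hafvf_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hafvf_trace <- function(object, ...) {
  df <- tibble::as_tibble(object)
  long <- dplyr::bind_rows(
    tibble::tibble(trial = df$trial, panel = "belief", quantity = "x",
                   value = df$x),
    tibble::tibble(trial = df$trial, panel = "belief",
                   quantity = "posterior mean", value = df$mu),
    tibble::tibble(trial = df$trial, panel = "forgetting",
                   quantity = "E[w]", value = df$w_hat),
    tibble::tibble(trial = df$trial, panel = "forgetting",
                   quantity = "E[b]", value = df$b_hat),
    tibble::tibble(trial = df$trial, panel = "memory (trials)",
                   quantity = "effective (kappa)", value = df$kappa),
    tibble::tibble(trial = df$trial, panel = "memory (trials)",
                   quantity = "efficient bound", value = df$eff_mem_w))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$trial, y = .data$value,
                                     colour = .data$quantity)) +
    ggplot2::geom_line(alpha = 0.9) +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "trial", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the speed-accuracy policy surface
#'
#' @param surface Output of [policy_surface()].
#' @return A ggplot object with accuracy and mean RT heat maps.
#' @export
plot_policy_surface <- function(surface) {
  long <- tidyr::pivot_longer(surface, c("accuracy", "mean_rt"),
                              names_to = "measure", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$kappa_j, y = .data$beta_j,
                                     fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~measure, scales = "free") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = expression(kappa[j]), y = expression(beta[j])) +
    ggplot2::theme_minimal()
}

#' Plot a flexibility study as a score table heat map
#'
#' @param results Output of [run_flexibility_experiments()].
#' @return A ggplot object.
#' @export
plot_flexibility <- function(results) {
  agg <- results |>
    dplyr::group_by(.data$experiment, .data$dataset, .data$agent) |>
    dplyr::summarise(mean_elbo = mean(.data$mean_elbo), .groups = "drop")
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$agent,
                                    y = factor(.data$dataset),
                                    fill = .data$mean_elbo)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.3f", .data$mean_elbo)), colour = "white") +
    ggplot2::facet_wrap(~experiment,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "agent (first/second-level memory)", y = "dataset",
                  fill = "mean ELBO") +
    ggplot2::theme_minimal()
}
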