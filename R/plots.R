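#' Plot a metabolite degree distribution
#'
#' Log-log points-and-lines plot of degree frequencies, the usual view for
#' judging heavy-tailed (scale-free-like) distributions.
#'
#' @param object A `degree_histogram` from [degree_distribution()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.degree_histogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$degree, y = .data$frequency)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "metabolite degree", y = "frequency") +
    ggplot2::theme_minimal()
}

#' Plot a normalized flux histogram
#'
#' @param object A `flux_histogram` from [flux_distribution()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.flux_histogram <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = (.data$lower + .data$upper) / 2,
                               y = .data$frequency)) +
    ggplot2::geom_col(width = 0.1, fill = "grey40") +
    ggplot2::labs(x = "|flux| / max |flux|", y = "frequency") +
    ggplot2::theme_minimal()
}

#' Plot pruning trajectories
#'
#' Reaction counts per pruning iteration for one or more pruned networks (or
#' ensemble records), overlaid; useful for comparing how the two pruning
#' rules approach their final network sizes.
#'
#' @param x A `pruned_network`, a list of them, or a [run_ensemble()] tibble.
#' @return A ggplot object.
#' @export
plot_trajectories <- function(x) {
  if (inherits(x, "pruned_network")) x <- list(x)
  if (is.data.frame(x)) {
    traj <- x$trajectory
    labels <- paste0("b", x$biomass_set_id, ".n", x$nutrient_set_id)
  } else {
    traj <- lapply(x, `[[`, "trajectory")
    labels <- as.character(seq_along(traj))
  }
  df <- dplyr::bind_rows(purrr::map2(traj, labels, function(tr, lab) {
    if (length(tr) == 0L) return(NULL)
    tibble(run = lab, iteration = seq_along(tr) - 1L, n_reactions = tr)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$n_reactions,
                                   group = .data$run)) +
    ggplot2::geom_step(alpha = 0.4) +
    ggplot2::labs(x = "pruning iteration", y = "internal reactions retained") +
    ggplot2::theme_minimal()
}

#' Plot an aggregated degree or flux distribution with error bars
#'
#' @param aggregated A tibble from [aggregate_distributions()].
#' @param log Use log-log axes (sensible for degree distributions).
#' @return A ggplot object.
#' @export
plot_aggregate <- function(aggregated, log = TRUE) {
  key <- names(aggregated)[1]
  p <- ggplot2::ggplot(aggregated,
                       ggplot2::aes(x = .data[[key]], y = .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = pmax(.data$mean - .data$sd, 0),
      ymax = .data$mean + .data$sd)) +
    ggplot2::labs(x = key, y = "mean frequency") +
    ggplot2::theme_minimal()
  if (log) p <- p + ggplot2::scale_x_log10() + ggplot2::scale_y_log10()
  p
}
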