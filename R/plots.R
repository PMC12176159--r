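# ggplot2 views of the main result types.

#' @describeIn phmm_fit Plot the fitted state-dependent densities per
#'   feature (joint log-normal emissions are shown as per-feature marginal
#'   log-normals).
#' @param object A `wlphmm_fit`.
#' @param from,to Range of the evaluation grid (defaults chosen per feature
#'   from the fitted parameters).
#' @export
autoplot.wlphmm_fit <- function(object, from = NULL, to = NULL, ...) {
  spec <- object$spec
  em <- spec$emission
  grids <- list()
  for (k in seq_along(em$features)) {
    f <- em$features[[k]]
    for (i in seq_len(spec$n_states)) {
      th <- object$params$theta[[i]]
      if (!is.null(em$joint)) {
        mu <- th$meanlog[k]
        s <- sqrt(th$sigmalog[k, k])
        lo <- from %||% exp(mu - 3 * s)
        hi <- to %||% exp(mu + 3 * s)
        x <- seq(lo, hi, length.out = 200)
        dens <- stats::dlnorm(x, mu, s)
      } else {
        p <- th[[f]]
        fam <- em$family[[f]]
        rng <- switch(fam,
          normal = p[["mean"]] + c(-4, 4) * p[["sd"]],
          gamma = c(1e-6, p[["mean"]] + 4 * p[["sd"]]),
          shifted_t = p[["location"]] + c(-5, 5))
        x <- seq(from %||% rng[1], to %||% rng[2], length.out = 200)
        dens <- switch(fam,
          normal = dnorm(x, p[["mean"]], p[["sd"]]),
          gamma = {
            sr <- gamma_shape_rate(p[["mean"]], p[["sd"]])
            dgamma(x, shape = sr[["shape"]], rate = sr[["rate"]])
          },
          shifted_t = dt(x - p[["location"]], df = p[["df"]]))
      }
      grids[[length(grids) + 1]] <- tibble::tibble(
        feature = f, state = spec$state_names[i], x = x, density = dens)
    }
  }
  d <- dplyr::bind_rows(grids)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$density,
                                  colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~feature, scales = "free") +
    ggplot2::labs(x = NULL, y = "density",
                  title = sprintf("State-dependent densities (alpha = %g)",
                                  object$alpha)) +
    ggplot2::theme_minimal()
}

#' @describeIn phmm_cv Plot the cross-validated metrics against alpha.
#' @param object A `wlphmm_cv`.
#' @export
autoplot.wlphmm_cv <- function(object, ...) {
  d <- tidyr::pivot_longer(object$metrics,
                           cols = c("sensitivity", "specificity", "auc"),
                           names_to = "metric", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$alpha), y = .data$value,
                                  colour = .data$state, group = .data$state)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = "alpha", y = NULL,
                  title = "Cross-validated metrics by likelihood weight") +
    ggplot2::theme_minimal()
}

#' Plot simulation-experiment AUC distributions
#'
#' Boxplots of test-set AUC per weight, one panel per experiment.
#'
#' @param results Output of [run_experiment()] (optionally row-bound across
#'   experiments with an `experiment` column).
#' @return A ggplot object.
#' @export
plot_experiment_auc <- function(results) {
  p <- ggplot2::ggplot(dplyr::filter(results, !.data$failed),
                       ggplot2::aes(x = factor(.data$alpha), y = .data$auc)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = "alpha", y = "test-set AUC") +
    ggplot2::theme_minimal()
  if ("experiment" %in% names(results)) {
    p <- p + ggplot2::facet_wrap(~experiment)
  }
  p
}

#' Plot a decoded dive or series profile
#'
#' Lines of one feature over time coloured by the Viterbi-decoded state.
#'
#' @param data Labelled-series data frame.
#' @param decoded Tibble from [phmm_viterbi()].
#' @param feature Feature column to draw.
#' @return A ggplot object.
#' @export
plot_decoded <- function(data, decoded, feature) {
  d <- as.data.frame(data)
  if (!"series_id" %in% names(d)) d$series_id <- "series1"
  if (!"t" %in% names(d)) d$t <- seq_len(nrow(d))
  d <- dplyr::left_join(d, decoded, by = c("series_id", "t"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t, y = .data[[feature]],
                                  colour = .data$state)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~series_id, scales = "free_x") +
    ggplot2::labs(x = "t", y = feature) +
    ggplot2::theme_minimal()
}
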