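# ggplot2 displays for trajectories and null calibrations.

#' @rdname sequential_bf
#' @param object A `seqbf_curve`.
#' @param threshold Stopping threshold drawn as dashed evidence boundaries.
#' @method autoplot seqbf_curve
#' @export
autoplot.seqbf_curve <- function(object, threshold = object$config$stop_bf, ...) {
  d <- object$data
  ggplot2::ggplot(d, ggplot2::aes(x = .data$cumulative_n, y = .data$bf10)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 1, colour = "grey60") +
    ggplot2::geom_hline(yintercept = c(threshold, 1 / threshold),
                        linetype = 2, colour = "grey40") +
    ggplot2::geom_line(colour = "#b2182b") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "cumulative sample size",
                  y = expression(BF[10]),
                  title = "Sequential Bayes factor",
                  subtitle = sprintf("Cauchy(0, %g) prior, direction = %s",
                                     object$config$prior_scale,
                                     object$config$direction)) +
    ggplot2::theme_minimal()
}

#' @rdname build_null
#' @param object A `seqbf_null`.
#' @param observed Optional one-row [anomaly_stats()] tibble drawn as
#'   vertical reference lines.
#' @method autoplot seqbf_null
#' @export
autoplot.seqbf_null <- function(object, observed = NULL, ...) {
  s <- object$stats |>
    dplyr::mutate(max_bf = log10(.data$max_bf), energy = asinh(.data$energy)) |>
    tidyr::pivot_longer(c("max_bf", "energy", "amp_sum"),
                        names_to = "statistic", values_to = "value")
  p <- ggplot2::ggplot(s, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_density(fill = "grey80", colour = "grey30") +
    ggplot2::facet_wrap(~statistic, scales = "free",
                        labeller = ggplot2::as_labeller(c(
                          max_bf = "log10 max BF", energy = "asinh energy",
                          amp_sum = "FFT amplitude sum"))) +
    ggplot2::labs(x = NULL, y = "density",
                  title = sprintf("Null distribution (%d simulations of %d participants)",
                                  object$n_sims, object$n_participants)) +
    ggplot2::theme_minimal()
  if (!is.null(observed)) {
    obs <- tibble(statistic = c("max_bf", "energy", "amp_sum"),
                  value = c(log10(observed$max_bf), asinh(observed$energy),
                            observed$amp_sum))
    p <- p + ggplot2::geom_vline(data = obs,
                                 ggplot2::aes(xintercept = .data$value),
                                 colour = "#b2182b")
  }
  p
}

#' Combined max-BF / energy scatter against the null cloud
#'
#' Scatter plot of log10 maximum BF against asinh curve energy for all null
#' simulations, with the observed pair highlighted and its joint-dominance
#' corner shaded.
#'
#' @param null A [build_null()] result.
#' @param observed One-row tibble with `max_bf` and `energy` (e.g.
#'   [anomaly_stats()]).
#' @return A ggplot object.
#' @export
plot_combined_scores <- function(null, observed = NULL) {
  stopifnot(inherits(null, "seqbf_null"))
  s <- null$stats
  p <- ggplot2::ggplot(s, ggplot2::aes(x = log10(.data$max_bf),
                                       y = asinh(.data$energy))) +
    ggplot2::geom_point(colour = "grey50", alpha = 0.5, size = 0.8) +
    ggplot2::labs(x = expression(log[10] ~ "max" ~ BF[10]),
                  y = "asinh(curve energy)",
                  title = "Combined anomaly scores") +
    ggplot2::theme_minimal()
  if (!is.null(observed)) {
    p <- p +
      ggplot2::annotate("rect", xmin = log10(observed$max_bf),
                        xmax = Inf, ymin = asinh(observed$energy), ymax = Inf,
                        fill = "#2166ac", alpha = 0.15) +
      ggplot2::annotate("point", x = log10(observed$max_bf),
                        y = asinh(observed$energy), colour = "#b2182b", size = 2)
  }
  p
}
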