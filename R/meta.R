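# Per-lab Bayes factors and random-effects meta-analysis of the avoidance
# effect across labs.

#' Per-lab summary rows from a cohort
#'
#' Aggregates a participant table into one row per lab: sample size, mean
#' negative-outcome count, and standard deviation (n - 1 denominator).
#'
#' @param cohort Participant data frame with columns `lab` and
#'   `negative_count`.
#' @return Tibble with columns `label`, `n`, `mean`, `sd`, ordered by
#'   decreasing `n`.
#' @examples
#' lab_summaries(simulate_cohort(labs = c(A = 50, B = 30), seed = 1))
#' @export
lab_summaries <- function(cohort) {
  if (!all(c("lab", "negative_count") %in% names(cohort))) {
    abort("`cohort` must have columns `lab` and `negative_count`.")
  }
  cohort |>
    dplyr::group_by(label = .data$lab) |>
    dplyr::summarise(n = dplyr::n(),
                     mean = mean(.data$negative_count),
                     sd = sd(.data$negative_count), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$n))
}

#' Per-lab one-sided Bayes factors from summary rows
#'
#' Computes, for each lab row, the one-sample t statistic against chance and
#' the one-sided Bayes factor with the analysis prior.
#'
#' @param labs Data frame with columns `label`, `n`, `mean`, `sd` (e.g.
#'   [lab_summaries()] or [replication_lab_table()]).
#' @param config A [bf_config()].
#' @return The input tibble with added columns `t`, `bf10`, `bf01`.
#' @examples
#' lab_bayes_factors(replication_lab_table())
#' @export
lab_bayes_factors <- function(labs, config = bf_config()) {
  stopifnot(inherits(config, "bf_config"))
  labs <- as_tibble(labs)
  if (!all(c("label", "n", "mean", "sd") %in% names(labs))) {
    abort("`labs` must have columns `label`, `n`, `mean`, `sd`.")
  }
  if (any(labs$n < 2)) abort("each lab must have n >= 2.")
  if (any(labs$sd <= 0)) abort("degenerate lab summary: `sd` must be positive.")
  labs |>
    dplyr::mutate(
      t = (.data$mean - config$mu0) / (.data$sd / sqrt(.data$n)),
      bf10 = bf10(.data$t, .data$n, prior_scale = config$prior_scale,
                  direction = config$direction),
      bf01 = 1 / .data$bf10)
}

#' Standardized avoidance effect sizes per lab
#'
#' Computes the standardized one-sample effect d = (mu0 - mean) / sd, signed
#' so that avoidance (counts below chance) is positive, together with its
#' approximate sampling variance v = 1/n + d^2 / (2n).
#'
#' @inheritParams lab_bayes_factors
#' @param mu0 Chance-level count.
#' @return The input tibble with added columns `d` and `v`.
#' @examples
#' effect_sizes(replication_lab_table())
#' @export
effect_sizes <- function(labs, mu0 = 30) {
  labs <- as_tibble(labs)
  if (!all(c("n", "mean", "sd") %in% names(labs))) {
    abort("`labs` must have columns `n`, `mean`, `sd`.")
  }
  if (any(labs$sd <= 0)) abort("`sd` must be positive.")
  labs |>
    dplyr::mutate(d = (mu0 - .data$mean) / .data$sd,
                  v = 1 / .data$n + .data$d^2 / (2 * .data$n))
}

#' Random-effects meta-analysis of per-lab effects
#'
#' Pools the standardized per-lab avoidance effects under a random-effects
#' model (fit via [metafor::rma()]), reporting the pooled effect with its
#' standard error and the heterogeneity statistics: the between-lab variance
#' tau^2, I^2, Cochran's Q with its degrees of freedom, and the chi-square
#' p-value of Q.
#'
#' The default estimator is REML (the [metafor::rma()] default); the
#' method-of-moments DerSimonian-Laird estimator is available via
#' `method = "DL"`.
#'
#' @inheritParams effect_sizes
#' @param method tau^2 estimator, `"REML"` or `"DL"`.
#' @return Object of class `seqbf_meta` wrapping the `rma` fit; [tidy()]
#'   returns the per-lab rows with weights, [glance()] the pooled result
#'   (`es`, `se`, `ci_lb`, `ci_ub`, `p`, `tau2`, `tau`, `I2`, `Q`, `df`,
#'   `p_Q`).
#' @examples
#' m <- meta_random_effects(replication_lab_table())
#' glance(m)
#' @export
meta_random_effects <- function(labs, mu0 = 30, method = c("REML", "DL")) {
  method <- match.arg(method)
  es <- effect_sizes(labs, mu0 = mu0)
  if (nrow(es) < 2L) abort("meta-analysis requires at least 2 labs.")
  fit <- metafor::rma(yi = es$d, vi = es$v, method = method)
  structure(list(fit = fit, data = es, method = method, mu0 = mu0),
            class = "seqbf_meta")
}

#' @export
print.seqbf_meta <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<seqbf_meta> %d labs, %s estimator\n", nrow(x$data), x$method))
  cat(sprintf("  pooled d = %.4f (SE %.4f), p = %.3f\n", g$es, g$se, g$p))
  cat(sprintf("  tau^2 = %.3g, I^2 = %.3g%%, Q(%d) = %.3f, p_Q = %.3f\n",
              g$tau2, g$I2, g$df, g$Q, g$p_Q))
  invisible(x)
}

#' @rdname meta_random_effects
#' @param x A `seqbf_meta` object.
#' @param ... Unused.
#' @method tidy seqbf_meta
#' @export
tidy.seqbf_meta <- function(x, ...) {
  dplyr::mutate(x$data, weight = stats::weights(x$fit))
}

#' @rdname meta_random_effects
#' @method glance seqbf_meta
#' @export
glance.seqbf_meta <- function(x, ...) {
  f <- x$fit
  tibble(k = f$k, es = as.numeric(f$b), se = f$se,
         ci_lb = f$ci.lb, ci_ub = f$ci.ub, p = f$pval,
         tau2 = f$tau2, tau = sqrt(f$tau2), I2 = f$I2,
         Q = f$QE, df = f$k - 1L, p_Q = f$QEp)
}
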