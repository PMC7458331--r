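# Bayes-factor engine: one-sample t against chance, one-sided scaled-Cauchy
# prior on the standardized effect size, evaluated sequentially.

# Gauss-Legendre nodes/weights on (0, 1), cached per order.
.gl_cache <- new.env(parent = emptyenv())
gauss_legendre01 <- function(k) {
  key <- as.character(k)
  if (!is.null(.gl_cache[[key]])) return(.gl_cache[[key]])
  i <- seq_len(k - 1L)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, k, k)
  J[cbind(i, i + 1L)] <- b
  J[cbind(i + 1L, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  out <- list(x = (e$values[ord] + 1) / 2, w = e$vectors[1, ord]^2)
  .gl_cache[[key]] <- out
  out
}

#' Configuration for the sequential Bayes-factor analysis
#'
#' Bundles the analysis parameters: the chance-level count `mu0` (half the
#' number of trials for fair bits), the Cauchy prior scale on the standardized
#' effect size, the test direction, and the minimum sample size at which a
#' Bayes factor is computed.
#'
#' @param prior_scale Scale `r` of the Cauchy(0, r) prior on the standardized
#'   effect size under H1.  The default 0.1 encodes the expectation of a very
#'   small avoidance effect.
#' @param mu0 Chance-level expected count (defaults to 30, i.e. 60 fair-bit
#'   trials).
#' @param direction `"less"` (below-chance counts support H1, the default),
#'   `"greater"`, or `"two_sided"`.
#' @param min_n Smallest cumulative sample size at which the Bayes factor is
#'   evaluated; below it the sequential curve is fixed at 1 (equipoise).  Must
#'   be at least 2 because the sample standard deviation is undefined at n = 1.
#' @param stop_bf Evidence threshold for the optional-stopping rule: data
#'   collection stops when BF10 >= `stop_bf` or BF10 <= 1/`stop_bf`.
#'
#' @return A list of class `"bf_config"`.
#' @examples
#' bf_config()
#' bf_config(prior_scale = 0.707, direction = "two_sided")
#' @export
bf_config <- function(prior_scale = 0.1, mu0 = 30, direction = c("less", "greater", "two_sided"),
                      min_n = 2L, stop_bf = 10) {
  if (!is.numeric(prior_scale) || length(prior_scale) != 1L || !is.finite(prior_scale) ||
      prior_scale <= 0) {
    abort("`prior_scale` must be a single positive number.")
  }
  direction <- match.arg(gsub("\\.", "_", direction[1L]), c("less", "greater", "two_sided"))
  if (!is.numeric(mu0) || length(mu0) != 1L || !is.finite(mu0)) {
    abort("`mu0` must be a single finite number.")
  }
  min_n <- as.integer(min_n)
  if (is.na(min_n) || min_n < 2L) abort("`min_n` must be an integer >= 2.")
  if (!is.numeric(stop_bf) || length(stop_bf) != 1L || stop_bf <= 1) {
    abort("`stop_bf` must be a single number > 1.")
  }
  structure(list(prior_scale = prior_scale, mu0 = mu0, direction = direction,
                 min_n = min_n, stop_bf = stop_bf),
            class = "bf_config")
}

#' @export
print.bf_config <- function(x, ...) {
  cat("<bf_config>\n")
  cat(sprintf("  prior:     Cauchy(0, %g), direction = %s\n", x$prior_scale, x$direction))
  cat(sprintf("  chance:    mu0 = %g\n", x$mu0))
  cat(sprintf("  min_n:     %d\n", x$min_n))
  cat(sprintf("  stopping:  BF threshold %g\n", x$stop_bf))
  invisible(x)
}

#' Summary statistics of a count sample against chance
#'
#' Computes the one-sample t statistic of a vector of per-participant counts
#' against the chance level `mu0`, with the usual n - 1 denominator for the
#' standard deviation.  When the sample is degenerate (`sd == 0`) the t
#' statistic is `NA`; downstream Bayes factors treat such samples as carrying
#' no evidence (BF = 1).
#'
#' @param counts Numeric vector of per-participant negative-outcome counts
#'   (length >= 2).
#' @param mu0 Chance-level expected count.
#' @return A one-row tibble with columns `n`, `mean`, `sd`, `t`, `df`.
#' @examples
#' summarize_counts(c(28, 30, 32))
#' @export
summarize_counts <- function(counts, mu0 = 30) {
  counts <- as.numeric(counts)
  if (length(counts) < 2L) abort("`counts` must have length >= 2.")
  if (anyNA(counts)) abort("`counts` must not contain missing values.")
  n <- length(counts)
  m <- mean(counts)
  s <- sd(counts)
  t <- if (s > 0) (m - mu0) / (s / sqrt(n)) else NA_real_
  tibble(n = n, mean = m, sd = s, t = t, df = n - 1)
}

# Entries where fixed-order quadrature under-resolves the integrand and the
# adaptive fallback is used instead: extreme t, tiny samples with moderate t,
# wide priors at large n (likelihood much narrower than the prior), or a
# likelihood peak far outside the prior scale (peak near the mapped endpoint).
.needs_adaptive <- function(t, df, r) {
  abs(t) > 4 | (df < 30 & abs(t) > 2.5) | (r^2 * (df + 1) > 50 & abs(t) > 2) |
    abs(t) > 3 * r * sqrt(df + 1)
}

# Marginal likelihood ratio via fixed Gauss-Legendre quadrature in
# theta = atan(-delta / r), which maps the (half-)Cauchy prior to a uniform
# density on (0, pi/2) and compactifies its tail exactly.  Log-space
# accumulation keeps extreme t values finite.  Vectorized over t/df/sqrt_n.
.bf10_gl <- function(t, df, sqrt_n, r, direction, nodes) {
  # the symmetric prior is split at the origin, so the two-sided marginal is
  # the half-sum of the two truncated ones; each half-line integral then has
  # the likelihood peak anchored at an interval endpoint where the nodes
  # cluster
  if (direction == "two_sided") {
    return((.bf10_gl(t, df, sqrt_n, r, "less", nodes) +
              .bf10_gl(t, df, sqrt_n, r, "greater", nodes)) / 2)
  }
  q <- gauss_legendre01(nodes)
  m <- length(t)
  th <- q$x * (pi / 2)                        # (0, pi/2), truncated prior doubled
  sgn <- if (direction == "less") -1 else 1
  NC <- outer(sgn * r * tan(th), sqrt_n)      # nodes x m
  TT <- matrix(t, nodes, m, byrow = TRUE)
  DF <- matrix(df, nodes, m, byrow = TRUE)
  L <- suppressWarnings(dt(TT, DF, ncp = NC, log = TRUE))
  L <- L + log(q$w)            # GL weights already sum to 1 on the mapped range
  top <- apply(L, 2L, max)
  log_m1 <- top + log(colSums(exp(sweep(L, 2L, top))))
  exp(log_m1 - dt(t, df, log = TRUE))
}

# Refinement fallback on the effect-size scale: composite Gauss-Legendre
# panels bracketing the likelihood peak, accumulated in log space.  Used
# where the prior-mapped fixed rule under-resolves the integrand; panel
# placement tracks the likelihood, so accuracy is uniform in (t, n, r).
.bf10_adaptive <- function(t, df, sqrt_n, r, direction) {
  if (direction == "greater") {        # mirror symmetry of the central null
    return(.bf10_adaptive(-t, df, sqrt_n, r, "less"))
  }
  if (direction == "two_sided") {
    return((.bf10_adaptive(t, df, sqrt_n, r, "less") +
              .bf10_adaptive(-t, df, sqrt_n, r, "less")) / 2)
  }
  # likelihood of delta peaks near t / sqrt(n); its scale in the
  # noncentrality widens at small df like sqrt((df + t^2) / df)
  w <- sqrt((df + t^2) / df) / sqrt_n
  ext <- (abs(t) + 16) * sqrt((df + t^2) / df) / sqrt_n + 12 * r
  p <- min(0, max(-ext, t / sqrt_n))
  # geometric cuts resolve the prior's own scale when it is much smaller
  # than the likelihood scale (half the prior mass sits within r of zero)
  k <- max(0L, ceiling(log10(ext / r)))
  prior_cuts <- -r * 10^(0:min(k, 15L))
  cuts <- sort(unique(pmin(0, pmax(-ext,
    c(-ext, p - 8 * w, p - 2 * w, p + 2 * w, p + 8 * w, prior_cuts, 0)))))
  q <- gauss_legendre01(48L)
  d <- unlist(lapply(seq_len(length(cuts) - 1L), function(i) {
    cuts[i] + q$x * (cuts[i + 1L] - cuts[i])
  }))
  lw <- unlist(lapply(seq_len(length(cuts) - 1L), function(i) {
    log(q$w) + log(cuts[i + 1L] - cuts[i])
  }))
  logf <- suppressWarnings(dt(t, df, ncp = d * sqrt_n, log = TRUE)) +
    dcauchy(d, 0, r, log = TRUE) + lw
  top <- max(logf)
  # truncated half-line prior, density doubled
  2 * exp(top + log(sum(exp(logf - top))) - dt(t, df, log = TRUE))
}

#' One-sided Bayes factor for a one-sample t statistic
#'
#' Computes BF10 = m1 / m0 where m0 is the density of the observed t statistic
#' under the central t distribution with `n - 1` degrees of freedom and m1 is
#' its marginal density under H1, obtained by integrating the noncentral-t
#' density over the Cauchy(0, `prior_scale`) prior on the standardized effect
#' size.  For the one-sided directions the prior is truncated to the
#' corresponding half-line and its density doubled; `"two_sided"` uses the
#' untruncated prior.
#'
#' The integral is evaluated by Gauss-Legendre quadrature after the change of
#' variable that maps the Cauchy prior to a uniform density on a finite
#' interval; configurations where the fixed rule under-resolves the integrand
#' (extreme t, very small n, wide priors at large n) are refined with adaptive
#' quadrature.
#'
#' @param t One-sample t statistic(s) against the chance level.
#' @param n Sample size(s), recycled against `t`; must be >= 2.
#' @param prior_scale Cauchy prior scale on the standardized effect size.
#' @param direction `"less"`, `"greater"`, or `"two_sided"`.
#' @param nodes Order of the fixed Gauss-Legendre rule.
#' @return Numeric vector of Bayes factors BF10 (positive; `1/bf10` is BF01).
#'   Non-finite t values (degenerate samples) yield BF = 1.
#' @examples
#' bf10(-0.3426, 2004)              # overall replication summary
#' bf10(0, 1413)                    # t = 0 at large n favors H0
#' 1 / bf10(-0.3426, 2004)          # BF01
#' @export
bf10 <- function(t, n, prior_scale = 0.1, direction = c("less", "greater", "two_sided"),
                 nodes = 48L) {
  direction <- match.arg(gsub("\\.", "_", direction[1L]),
                         c("less", "greater", "two_sided"))
  if (!is.numeric(prior_scale) || length(prior_scale) != 1L || prior_scale <= 0) {
    abort("`prior_scale` must be a single positive number.")
  }
  m <- max(length(t), length(n))
  t <- rep_len(as.numeric(t), m)
  n <- rep_len(as.numeric(n), m)
  if (any(n < 2, na.rm = TRUE)) abort("`n` must be >= 2 (df >= 1).")
  out <- rep(1, m)                       # degenerate samples carry no evidence
  ok <- is.finite(t)
  if (!any(ok)) return(out)
  df <- n[ok] - 1
  tv <- t[ok]
  sqn <- sqrt(n[ok])
  hard <- .needs_adaptive(tv, df, prior_scale)
  res <- numeric(length(tv))
  if (any(!hard)) {
    res[!hard] <- .bf10_gl(tv[!hard], df[!hard], sqn[!hard], prior_scale,
                           direction, nodes)
  }
  if (any(hard)) {
    res[hard] <- vapply(which(hard), function(i) {
      .bf10_adaptive(tv[i], df[i], sqn[i], prior_scale, direction)
    }, numeric(1))
  }
  out[ok] <- res
  out
}

#' Bayes factor from printed summary statistics
#'
#' Convenience wrapper computing the t statistic from a reported sample size,
#' mean, and standard deviation, then the Bayes factor via [bf10()].  All
#' arguments are vectorized.
#'
#' @param n,mean,sd Sample size, mean count, and standard deviation
#'   (n - 1 denominator) of the sample.
#' @param prior_scale,direction,mu0 See [bf_config()].
#' @return Numeric vector of BF10 values.
#' @examples
#' bf_from_summary(2004, 29.97, 3.92)   # ~0.23: moderate evidence for H0
#' @export
bf_from_summary <- function(n, mean, sd, prior_scale = 0.1,
                            direction = "less", mu0 = 30) {
  if (any(sd <= 0, na.rm = TRUE)) abort("`sd` must be positive.")
  t <- (mean - mu0) / (sd / sqrt(n))
  bf10(t, n, prior_scale = prior_scale, direction = direction)
}

#' Sequential Bayes-factor trajectory over an ordered cohort
#'
#' Recomputes the one-sided Bayes factor after each participant, in the order
#' of data collection.  The value at cumulative sample sizes below
#' `config$min_n`, and at degenerate prefixes with zero standard deviation, is
#' fixed at 1 (equipoise), so the trajectory has exactly one value per
#' participant.
#'
#' @param cohort Either a numeric vector of per-participant counts in
#'   collection order, or a participant data frame with columns
#'   `negative_count` and `collection_order` (checked to be sorted; see
#'   [read_participants()] for the schema).
#' @param config A [bf_config()].
#' @return An object of class `seqbf_curve`: a list with `data` (tibble with
#'   columns `cumulative_n`, `mean`, `sd`, `t`, `bf10`, `bf01`) and `config`.
#'   [tidy()] returns the tibble, [glance()] a one-row summary, and
#'   [autoplot()] the trajectory plot.
#' @examples
#' cohort <- simulate_cohort(labs = c(demo = 80), seed = 1)
#' curve <- sequential_bf(cohort)
#' glance(curve)
#' @export
sequential_bf <- function(cohort, config = bf_config()) {
  stopifnot(inherits(config, "bf_config"))
  counts <- .cohort_counts(cohort)
  N <- length(counts)
  if (N < config$min_n) {
    abort(sprintf("cohort has %d participants; at least min_n = %d required.",
                  N, config$min_n))
  }
  idx <- seq_len(N)
  cs <- cumsum(counts)
  cs2 <- cumsum(counts^2)
  mean_n <- cs / idx
  var_n <- c(NA_real_, pmax((cs2[-1L] - idx[-1L] * mean_n[-1L]^2) / (idx[-1L] - 1), 0))
  sd_n <- sqrt(var_n)
  t_n <- ifelse(!is.na(sd_n) & sd_n > 0,
                (mean_n - config$mu0) / (sd_n / sqrt(idx)), NA_real_)
  bf <- rep(1, N)
  eval_at <- idx >= config$min_n & is.finite(t_n)
  if (any(eval_at)) {
    bf[eval_at] <- bf10(t_n[eval_at], idx[eval_at],
                        prior_scale = config$prior_scale,
                        direction = config$direction)
  }
  structure(
    list(data = tibble(cumulative_n = idx, mean = mean_n, sd = sd_n,
                       t = t_n, bf10 = bf, bf01 = 1 / bf),
         config = config),
    class = "seqbf_curve")
}

# Accept a bare count vector or a participant data frame in collection order.
.cohort_counts <- function(cohort) {
  if (is.numeric(cohort)) {
    if (anyNA(cohort)) abort("counts must not contain missing values.")
    return(as.numeric(cohort))
  }
  if (is.data.frame(cohort)) {
    if (!all(c("negative_count", "collection_order") %in% names(cohort))) {
      abort("participant data must have columns `negative_count` and `collection_order`.")
    }
    ord <- cohort$collection_order
    if (is.unsorted(ord, strictly = TRUE)) {
      abort("participants are not sorted by `collection_order`; sort first (see `read_participants()`).")
    }
    return(as.numeric(cohort$negative_count))
  }
  abort("`cohort` must be a numeric vector of counts or a participant data frame.")
}

#' @export
print.seqbf_curve <- function(x, ...) {
  n <- nrow(x$data)
  fin <- x$data$bf10[n]
  cat(sprintf("<seqbf_curve> %d participants, Cauchy(0, %g), direction = %s\n",
              n, x$config$prior_scale, x$config$direction))
  cat(sprintf("  final BF10 = %.4g (BF01 = %.4g), max BF10 = %.4g at n = %d\n",
              fin, 1 / fin, max(x$data$bf10), which.max(x$data$bf10)))
  invisible(x)
}

#' @rdname sequential_bf
#' @param x A `seqbf_curve` object.
#' @param ... Unused.
#' @method tidy seqbf_curve
#' @export
tidy.seqbf_curve <- function(x, ...) x$data

#' @rdname sequential_bf
#' @method glance seqbf_curve
#' @export
glance.seqbf_curve <- function(x, ...) {
  n <- nrow(x$data)
  stop <- stopping_check(x, threshold = x$config$stop_bf)
  tibble(n = n,
         mean = x$data$mean[n], sd = x$data$sd[n], t = x$data$t[n],
         final_bf10 = x$data$bf10[n], final_bf01 = x$data$bf01[n],
         max_bf10 = max(x$data$bf10), max_at_n = which.max(x$data$bf10),
         decision = stop$decision, n_stop = stop$n_stop)
}

#' Optional-stopping evaluation of a sequential trajectory
#'
#' Applies the symmetric evidence-threshold stopping rule: data collection
#' stops at the first cumulative sample size where BF10 >= `threshold`
#' (stop for H1) or BF10 <= 1/`threshold` (stop for H0), whichever boundary is
#' crossed first.
#'
#' @param curve A [sequential_bf()] result or a numeric vector of BF10 values.
#' @param threshold Evidence threshold (> 1).
#' @return One-row tibble with `decision` (`"continue"`, `"stop_for_H1"`, or
#'   `"stop_for_H0"`), `n_stop` (first crossing index, `NA` if none), and
#'   `bf_at_stop`.
#' @examples
#' stopping_check(c(1, 2, 5, 12, 30))          # stops for H1 at n = 4
#' stopping_check(c(1, 0.5, 0.09), threshold = 10)
#' @export
stopping_check <- function(curve, threshold = 10) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 1) {
    abort("`threshold` must be a single number > 1.")
  }
  bf <- if (inherits(curve, "seqbf_curve")) curve$data$bf10 else as.numeric(curve)
  i1 <- which(bf >= threshold)[1L]
  i0 <- which(bf <= 1 / threshold)[1L]
  if (is.na(i1) && is.na(i0)) {
    return(tibble(decision = "continue", n_stop = NA_integer_, bf_at_stop = NA_real_))
  }
  if (is.na(i0) || (!is.na(i1) && i1 <= i0)) {
    tibble(decision = "stop_for_H1", n_stop = as.integer(i1), bf_at_stop = bf[i1])
  } else {
    tibble(decision = "stop_for_H0", n_stop = as.integer(i0), bf_at_stop = bf[i0])
  }
}

#' Early-terminating sequential analysis
#'
#' Equivalent to running [sequential_bf()] and [stopping_check()], but the
#' trajectory is evaluated in blocks and abandoned at the first boundary
#' crossing, which makes large simulation studies of the stopping rule cheap
#' when crossings occur early.
#'
#' @param counts Numeric vector of per-participant counts in collection order.
#' @param config A [bf_config()].
#' @param threshold Evidence threshold; defaults to `config$stop_bf`.
#' @param block Number of participants evaluated per block.
#' @return Same one-row tibble as [stopping_check()].
#' @export
sequential_stop <- function(counts, config = bf_config(), threshold = config$stop_bf,
                            block = 256L) {
  counts <- .cohort_counts(counts)
  N <- length(counts)
  from <- config$min_n
  while (from <= N) {
    to <- min(N, from + block - 1L)
    idx <- from:to
    cs <- cumsum(counts)[idx]
    cs2 <- cumsum(counts^2)[idx]
    m <- cs / idx
    s2 <- pmax((cs2 - idx * m^2) / (idx - 1), 0)
    t <- ifelse(s2 > 0, (m - config$mu0) / (sqrt(s2 / idx)), NA_real_)
    bf <- bf10(t, idx, prior_scale = config$prior_scale, direction = config$direction)
    i1 <- which(bf >= threshold)[1L]
    i0 <- which(bf <= 1 / threshold)[1L]
    if (!is.na(i1) || !is.na(i0)) {
      if (is.na(i0) || (!is.na(i1) && i1 <= i0)) {
        return(tibble(decision = "stop_for_H1", n_stop = as.integer(idx[i1]),
                      bf_at_stop = bf[i1]))
      }
      return(tibble(decision = "stop_for_H0", n_stop = as.integer(idx[i0]),
                    bf_at_stop = bf[i0]))
    }
    from <- to + 1L
  }
  tibble(decision = "continue", n_stop = NA_integer_, bf_at_stop = NA_real_)
}

#' Prior-robustness sweep over Cauchy scales
#'
#' Recomputes the final Bayes factor under a grid of prior scales, the
#' standard check that a null result is not an artifact of a narrow prior.
#'
#' @param x Either a numeric vector of counts or a one-row summary data frame
#'   with columns `n`, `mean`, `sd` (e.g. from [summarize_counts()]).
#' @param prior_scales Positive Cauchy scales; the default grid spans the
#'   conventional narrow, medium, wide, and ultrawide settings.
#' @param direction,mu0 See [bf_config()].
#' @return Tibble with columns `prior_scale`, `bf10`, `bf01`.
#' @examples
#' robustness_sweep(tibble::tibble(n = 2004, mean = 29.97, sd = 3.92))
#' @export
robustness_sweep <- function(x, prior_scales = c(0.1, 0.707, 1, 1.414),
                             direction = "less", mu0 = 30) {
  if (length(prior_scales) == 0L || any(!is.finite(prior_scales)) ||
      any(prior_scales <= 0)) {
    abort("`prior_scales` must be a non-empty vector of positive numbers.")
  }
  s <- if (is.data.frame(x)) {
    if (!all(c("n", "mean", "sd") %in% names(x)) || nrow(x) != 1L) {
      abort("summary input must be a one-row data frame with columns `n`, `mean`, `sd`.")
    }
    x
  } else {
    summarize_counts(x, mu0 = mu0)
  }
  bf <- vapply(prior_scales, function(r) {
    bf_from_summary(s$n, s$mean, s$sd, prior_scale = r,
                    direction = direction, mu0 = mu0)
  }, numeric(1))
  tibble(prior_scale = prior_scales, bf10 = bf, bf01 = 1 / bf)
}
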