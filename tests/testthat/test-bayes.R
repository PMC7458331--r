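test_that("count summaries give the one-sample t against chance", {
  s <- summarize_counts(c(28, 30, 32), mu0 = 30)
  expect_equal(s$n, 3)
  expect_equal(s$mean, 30)
  expect_equal(s$t, 0)           # symmetric sample around chance
  expect_equal(s$df, 2)

  s2 <- summarize_counts(c(25, 27, 29), mu0 = 27)
  expect_equal(s2$t, 0)

  # degenerate sample: t undefined, flagged as NA
  expect_true(is.na(summarize_counts(c(28, 28, 28))$t))
  expect_error(summarize_counts(30), "length")
})

test_that("Bayes factors reproduce the printed summary-based values", {
  # overall replication sample: n = 2004, M = 29.97, SD = 3.92 -> BF10 = 0.23
  t_all <- (29.97 - 30) / (3.92 / sqrt(2004))
  expect_equal(t_all, -0.3426, tolerance = 1e-3)
  expect_equal(bf10(t_all, 2004), 0.23, tolerance = 0.02)
  expect_equal(bf_from_summary(2004, 29.97, 3.92), 0.23, tolerance = 0.02)

  # per-lab rows; tolerance covers the 2-decimal rounding of the summaries
  tab <- lab_bayes_factors(replication_lab_table())
  expect_true(all(abs(tab$bf10 - tab$bf10_reported) < 0.05))
  expect_equal(tab$bf10[tab$label == "Germany"], 0.20, tolerance = 0.005)
})

test_that("one-sided components average to the two-sided Bayes factor", {
  grid <- expand.grid(t = c(-2, -0.5, 0, 1, 3), n = c(10, 200, 2004),
                      r = c(0.1, 0.707))
  for (i in seq_len(nrow(grid))) {
    less <- bf10(grid$t[i], grid$n[i], grid$r[i], direction = "less")
    greater <- bf10(grid$t[i], grid$n[i], grid$r[i], direction = "greater")
    two <- bf10(grid$t[i], grid$n[i], grid$r[i], direction = "two_sided")
    expect_equal(less + greater, 2 * two, tolerance = 1e-6)
  }
  # at t = 0 all three coincide
  expect_equal(bf10(0, 154, direction = "less"),
               bf10(0, 154, direction = "greater"), tolerance = 1e-9)
  expect_equal(bf10(0, 154, direction = "less"),
               bf10(0, 154, direction = "two_sided"), tolerance = 1e-9)
})

test_that("the directional Bayes factor is strictly decreasing in t", {
  t <- seq(-4, 4, by = 0.25)
  bf <- bf10(t, 154, direction = "less")
  expect_true(all(diff(bf) < 0))
})

test_that("the Bayes factor collapses to 1 as the prior shrinks onto the null", {
  for (t in c(-2, 0, 1.5)) {
    expect_equal(bf10(t, 154, prior_scale = 1e-8), 1, tolerance = 1e-3)
  }
})

test_that("BF is continuous in the prior scale", {
  b1 <- bf10(-1.652, 154, prior_scale = 0.1)
  b2 <- bf10(-1.652, 154, prior_scale = 0.1 + 1e-6)
  expect_lt(abs(b1 - b2), 1e-4)
})

test_that("production quadrature matches the brute-force trapezoid oracle", {
  for (t in c(-1.652, 0, 1)) {
    for (n in c(10, 154, 2004)) {
      for (r in c(0.05, 0.1, 0.707)) {
        expect_equal(bf10(t, n, prior_scale = r),
                     bf10_trapezoid(t, n, r),
                     tolerance = 1e-5,
                     label = sprintf("bf10(t=%g, n=%d, r=%g)", t, n, r))
      }
    }
  }
})

test_that("extreme statistics route through the adaptive fallback accurately", {
  cases <- list(c(-9, 2), c(-20, 4), c(-8, 2328))
  for (cs in cases) {
    expect_equal(bf10(cs[1], cs[2]),
                 bf10_trapezoid(cs[1], cs[2], 0.1, n_grid = 200000L),
                 tolerance = 1e-4,
                 label = sprintf("bf10(t=%g, n=%d)", cs[1], cs[2]))
  }
  # far wrong-direction tail: the noncentral-t density itself is only good to
  # ~1e-4 relative here, which bounds what any quadrature can achieve
  expect_equal(bf10(6, 1000), bf10_trapezoid(6, 1000, 0.1, n_grid = 200000L),
               tolerance = 1e-3)
  # wide prior at large n (narrow likelihood inside a broad prior)
  expect_equal(bf10(-3, 2004, prior_scale = 1.414),
               bf10_trapezoid(-3, 2004, 1.414, n_grid = 200000L),
               tolerance = 1e-5)
})

test_that("sequential curve matches prefix-wise recomputation", {
  set.seed(31)
  counts <- simulate_null_counts(120, seed = 31)
  curve <- sequential_bf(counts)
  expect_s3_class(curve, "seqbf_curve")
  expect_equal(nrow(curve$data), 120L)
  expect_equal(curve$data$bf10[1L], 1)     # below min_n: equipoise
  for (n in c(2L, 37L, 120L)) {
    s <- summarize_counts(counts[1:n])
    expected <- if (is.na(s$t)) 1 else bf10(s$t, n)
    expect_equal(curve$data$bf10[n], expected, tolerance = 1e-9)
    expect_equal(curve$data$mean[n], s$mean)
    expect_equal(curve$data$sd[n], s$sd)
  }
  expect_true(all(curve$data$bf10 > 0))
  expect_equal(curve$data$bf01, 1 / curve$data$bf10)
})

test_that("a cohort pinned at chance yields a decreasing evidence curve", {
  curve <- sequential_bf(rep(30, 50))
  # sd = 0 prefixes are equipoise by convention
  expect_true(all(curve$data$bf10 == 1))

  # alternate exactly around chance: t = 0 whenever n is even
  curve2 <- sequential_bf(rep(c(28, 32), 40))
  even <- seq(2, 80, by = 2)
  expect_equal(curve2$data$t[even], rep(0, length(even)))
  expect_true(all(diff(curve2$data$bf10[even]) < 0))
})

test_that("degenerate prefixes carry no evidence", {
  counts <- c(28, 28, 28, 30, 32, 27, 29)
  curve <- sequential_bf(counts)
  expect_equal(curve$data$bf10[1:3], rep(1, 3))   # sd = 0 at n = 2, 3
  expect_false(curve$data$bf10[4] == 1)
})

test_that("cohort input is validated", {
  co <- simulate_cohort(labs = c(A = 10), seed = 2)
  expect_silent(sequential_bf(co))
  shuffled <- co[c(3, 1, 2, 4:10), ]
  expect_error(sequential_bf(shuffled), "collection_order")
  expect_error(sequential_bf(c(30)), "min_n")
  expect_error(bf10(0, 1), "n")
  expect_error(bf10(0, 10, prior_scale = -1), "prior_scale")
})

test_that("stopping rule reports the first boundary crossing", {
  expect_equal(stopping_check(c(1, 2, 5, 12, 30))$decision, "stop_for_H1")
  expect_equal(stopping_check(c(1, 2, 5, 12, 30))$n_stop, 4L)
  s0 <- stopping_check(c(1, 0.5, 0.09, 20))
  expect_equal(s0$decision, "stop_for_H0")   # H0 boundary crossed first
  expect_equal(s0$n_stop, 3L)
  expect_equal(stopping_check(rep(1, 10))$decision, "continue")
  expect_error(stopping_check(c(1, 2), threshold = 1), "threshold")
})

test_that("early-terminating stopping agrees with the full curve", {
  p <- p_negative_for_effect(0.35)
  for (seed in c(1, 2, 3)) {
    co <- simulate_cohort(labs = c(L = 300), p_negative = p, seed = seed)
    full <- stopping_check(sequential_bf(co))
    fast <- sequential_stop(co$negative_count, block = 64L)
    expect_equal(fast$decision, full$decision)
    expect_equal(fast$n_stop, full$n_stop)
  }
})

test_that("robustness sweep spans the prior grid consistently", {
  set.seed(77)
  counts <- simulate_null_counts(200, seed = 77)
  sw <- robustness_sweep(counts)
  expect_equal(sw$prior_scale, c(0.1, 0.707, 1, 1.414))
  expect_equal(sw$bf01, 1 / sw$bf10)
  # a single-element grid reproduces the main analysis value
  s <- summarize_counts(counts)
  expect_equal(robustness_sweep(counts, prior_scales = 0.1)$bf10,
               bf10(s$t, s$n), tolerance = 1e-9)
  # summary input and raw counts agree
  expect_equal(robustness_sweep(s)$bf10, sw$bf10, tolerance = 1e-9)
  expect_error(robustness_sweep(counts, prior_scales = numeric(0)), "prior_scales")
  expect_error(robustness_sweep(counts, prior_scales = c(0.1, -1)), "prior_scales")
})
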