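test_that("curve energy is the signed area against equipoise", {
  expect_equal(curve_energy(rep(1, 100)), 0)
  b <- 7.5
  spike <- c(rep(1, 40), b, rep(1, 59))
  expect_equal(curve_energy(spike), b - 1)
  expect_equal(curve_energy(c(0.5, 0.5)), -1)
  expect_error(curve_energy(numeric(0)), "non-empty")
})

test_that("maximum statistic reports the first attainment", {
  st <- anomaly_stats(c(1, 5, 5, 2))
  expect_equal(st$max_bf, 5)
  expect_equal(st$max_at_n, 2L)          # ties broken by smallest index
  mono <- anomaly_stats(seq(0.1, 2, length.out = 8))
  expect_equal(mono$max_at_n, 8L)        # monotone series peaks at the end
  const <- anomaly_stats(rep(1, 6))
  expect_equal(const$max_at_n, 1L)
})

test_that("amplitude spectrum recovers pure oscillations", {
  N <- 64
  expect_true(all(amplitude_spectrum(rep(3, N))$amplitude < 1e-12))

  A <- 2.5; k0 <- 5
  s <- A * cos(2 * pi * k0 * (0:(N - 1)) / N)
  sp <- amplitude_spectrum(s, scaling = "amplitude")
  expect_equal(nrow(sp), N / 2)
  expect_equal(sp$amplitude[k0], A, tolerance = 1e-10)
  expect_lt(max(sp$amplitude[-k0]), 1e-10)

  # under the halved normalization the bin reads A/2
  expect_equal(amplitude_spectrum(s)$amplitude[k0], A / 2, tolerance = 1e-10)

  expect_error(amplitude_spectrum(c(1, 2)), "length")
})

test_that("spectrum satisfies Parseval and reconstructs the series", {
  set.seed(12)
  x <- rnorm(256)
  sp <- amplitude_spectrum(x, scaling = "amplitude")
  N <- length(x)
  # population variance = sum of squared amplitudes (cosine terms carry a_k^2/2,
  # the unmirrored Nyquist term a^2)
  v <- sum(sp$amplitude[-(N / 2)]^2) / 2 + sp$amplitude[N / 2]^2
  expect_equal(v, mean(x^2) - mean(x)^2, tolerance = 1e-8)

  # the retained half plus conjugate symmetry reconstructs the raw series
  co <- fft(x)
  rebuilt <- c(co[1:(N / 2 + 1)], Conj(co[(N / 2):2]))
  expect_equal(Re(fft(rebuilt, inverse = TRUE)) / N, x, tolerance = 1e-8)
})

test_that("odd-length series are padded by repeating the last value", {
  x <- c(1, 2, 3, 2, 1, 2, 4)
  expect_equal(amplitude_spectrum(x)$amplitude,
               amplitude_spectrum(c(x, 4))$amplitude)
  expect_equal(nrow(amplitude_spectrum(x)), 4L)
})

test_that("amplitude sum is linear in the series", {
  set.seed(13)
  x <- rnorm(128)
  expect_equal(amp_sum(2 * x), 2 * amp_sum(x), tolerance = 1e-10)
  expect_equal(amp_sum(rep(5, 32)), 0, tolerance = 1e-12)
  # DC exclusion makes a constant shift irrelevant
  expect_equal(amp_sum(x + 100), amp_sum(x), tolerance = 1e-7)
})

test_that("empirical p-values use the inclusive convention", {
  expect_equal(empirical_p(2, c(1, 2, 3, 4)), 0.75)
  expect_equal(empirical_p(5, 5), 1)               # tie with a single value
  expect_equal(empirical_p(0, c(1, 2, 3)), 1)       # below every null value
  expect_equal(empirical_p(10, c(1, 2, 3)), 0)      # above every null value
  expect_error(empirical_p(c(1, 2), 1:3), "single")
  expect_error(empirical_p(1, numeric(0)), "non-empty")
})

test_that("joint exceedance is a corner-region dominance proportion", {
  nd <- tibble::tibble(max_bf = c(1, 5, 20, 50), energy = c(-10, 40, 100, 30))
  # inclusive dominance: (5,40), (20,100), and the energy tie (50,30) count
  expect_equal(combined_exceedance(c(max_bf = 4, energy = 30), nd), 0.75)
  expect_equal(combined_exceedance(c(max_bf = 4, energy = 31), nd), 0.5)
  expect_equal(combined_exceedance(c(max_bf = 0, energy = -100), nd), 1)
  expect_equal(combined_exceedance(c(max_bf = 100, energy = 1000), nd), 0)
  # never exceeds either marginal exceedance
  obs <- c(max_bf = 4, energy = 35)
  expect_lte(combined_exceedance(obs, nd),
             min(empirical_p(obs["max_bf"], nd$max_bf),
                 empirical_p(obs["energy"], nd$energy)))
  # dominance is invariant under the monotone display transforms
  nd_t <- tibble::tibble(max_bf = log(nd$max_bf), energy = asinh(nd$energy))
  expect_equal(combined_exceedance(c(max_bf = log(4), energy = asinh(35)), nd_t),
               combined_exceedance(obs, nd))
})

test_that("null distributions are reproducible from the master seed", {
  a <- build_null(n_sims = 3, n_participants = 100, seed = 5)
  b <- build_null(n_sims = 3, n_participants = 100, seed = 5)
  expect_identical(a$stats, b$stats)
  expect_equal(nrow(a$stats), 3L)
  expect_true(all(a$stats$max_bf > 0))
  expect_true(all(is.finite(a$stats$energy)))
  expect_true(all(a$stats$amp_sum >= 0))
  c_ <- build_null(n_sims = 3, n_participants = 100, seed = 6)
  expect_false(identical(a$stats, c_$stats))
  expect_error(build_null(0, 100), "n_sims")
})

test_that("anomaly_test assembles observed statistics with calibrated p-values", {
  nd <- build_null(n_sims = 5, n_participants = 100, seed = 3)
  curve <- sequential_bf(simulate_null_counts(100, seed = 77))
  res <- anomaly_test(curve, nd)
  expect_true(all(c("p_max_bf", "p_energy", "p_amp_sum", "p_combined") %in% names(res)))
  ps <- unlist(res[c("p_max_bf", "p_energy", "p_amp_sum", "p_combined")])
  expect_true(all(ps >= 0 & ps <= 1))
  expect_lte(res$p_combined, min(res$p_max_bf, res$p_energy))
  # length mismatch is tolerated but flagged
  short <- sequential_bf(simulate_null_counts(60, seed = 78))
  expect_warning(anomaly_test(short, nd), "differs")
})

test_that("interpolated simulation engine matches exact quadrature", {
  fast <- build_null(n_sims = 3, n_participants = 250, seed = 17)
  slow <- build_null(n_sims = 3, n_participants = 250, seed = 17, engine = "exact")
  expect_equal(fast$stats$max_bf, slow$stats$max_bf, tolerance = 1e-4)
  expect_equal(fast$stats$max_at_n, slow$stats$max_at_n)
  expect_equal(fast$stats$energy, slow$stats$energy, tolerance = 1e-4)
  expect_equal(fast$stats$amp_sum, slow$stats$amp_sum, tolerance = 1e-4)

  # curve-level agreement of the two engines
  cfg <- bf_config()
  tab <- seqbf:::.make_bf_table(250, cfg)
  counts <- simulate_null_counts(250, seed = 19)
  expect_equal(seqbf:::.fast_curve(counts, cfg, tab),
               sequential_bf(counts, cfg)$data$bf10, tolerance = 1e-5)
})
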