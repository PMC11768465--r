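test_that("FFT convolution matches the O(n^2) oracle", {
  set.seed(1)
  for (n in c(64L, 256L)) {
    a <- runif(n); b <- runif(n)
    fast <- flimgate:::conv_fft(a, b, dt = 0.05)
    slow <- direct_conv(a, b, dt = 0.05)
    expect_lt(max(abs(fast - slow)) / max(abs(slow)), 1e-10)
  }
})

test_that("simulated decay reduces to the exponential for a delta-like IRF", {
  g <- time_grid(0, 0.05, 600L)
  tr <- simulate_decay(1, 1, irf_params(2, 0.05, 4), g)
  pk <- find_peak(tr)
  post <- tr$values[pk:(pk + 200L)]
  ref <- exp(-(0:200) * g$dt / 1)
  expect_equal(post / post[1], ref, tolerance = 1e-6)
})

test_that("simulated decay is linear in amplitude and single-peaked", {
  g <- time_grid(0, 0.05, 600L)
  p <- irf_params(10, 4.2, 4)
  t1 <- simulate_decay(1.3, 30, p, g)
  t2 <- simulate_decay(1.3, 60, p, g)
  expect_equal(t2$values, 2 * t1$values)
  expect_true(all(t1$values >= 0))
  pk <- find_peak(t1)
  expect_true(all(diff(t1$values[pk:g$n_bins]) <= 1e-9))
})

test_that("Poisson noise preserves the mean, yields integer counts, and zero stays zero", {
  g <- time_grid(0, 1, 3L)
  tr <- dense_trace(c(50, 50, 50), g)
  set.seed(11)
  draws <- replicate(10000, add_poisson_noise(tr)$values[1])
  se <- sqrt(50 / 10000)
  expect_lt(abs(mean(draws) - 50), 4 * se)
  expect_true(all(draws == round(draws)))

  z <- dense_trace(c(0, 0, 0), g)
  expect_equal(add_poisson_noise(z)$values, c(0, 0, 0))
  expect_error(add_poisson_noise(tr, background = -1), ">= 0")
})

test_that("SNR is the square root of the total count", {
  expect_equal(compute_snr(c(4, 9, 12)), 5)
  expect_warning(s0 <- compute_snr(c(0, 0)), "all-zero")
  expect_equal(s0, 0)
  expect_equal(snr_db(c(0, 0, 100)), 20)  # 10 * log10(100)
  # noiseless expectation: SNR equals sqrt(A * sum of normalized shape)
  g <- time_grid(0, 0.05, 600L)
  tr <- simulate_decay(1.5, 1, irf_params(10, 4.25, 4), g)
  shape <- tr$values / max(tr$values)
  A <- 57
  expect_equal(compute_snr(A * shape), sqrt(A * sum(shape)))
})

test_that("peak finding returns the earliest global maximum", {
  expect_equal(find_peak(exp(-(0:50) / 5)), 1L)
  expect_equal(find_peak(c(0, 1, 2, 3, 2, 1, 0)), 4L)
  expect_equal(find_peak(c(0, 5, 5, 1)), 2L)  # earliest tie
  g <- time_grid(0, 0.05, 600L)
  tr <- simulate_decay(1, 40, irf_params(10, 4, 4), g)
  expect_equal(find_peak(tr), which.max(tr$values))
  expect_error(find_peak(numeric(0)), "empty")
})

test_that("gate sampling is geometric on a pure exponential and shift invariant", {
  g <- time_grid(0, 0.05, 600L)
  tau <- 1.5
  tr <- exp(-g$t / tau)
  gates <- sample_gates(tr, 1L, gate_spacing = 1, dt = g$dt)
  r <- exp(-1 / tau)
  expect_equal(gates, r^(0:5))
  expect_equal(max(gates), 1)

  # tau = 1, spacing 1 -> consecutive ratio exp(-1)
  g1 <- sample_gates(exp(-g$t / 1), 1L, 1, dt = g$dt)
  expect_equal(g1[2:6] / g1[1:5], rep(exp(-1), 5))

  # shifting the trace leaves the peak-aligned samples unchanged
  shifted <- c(numeric(40), tr[1:(length(tr) - 40)])
  expect_identical(sample_gates(shifted, find_peak(shifted), 1, dt = g$dt),
                   sample_gates(tr, find_peak(tr), 1, dt = g$dt))

  expect_error(sample_gates(tr, 580L, 1, dt = g$dt), "insufficient tail")
  expect_error(sample_gates(tr, 1L, 0.033, dt = g$dt), "integer multiple")
})

test_that("ground-truth maps respect the configured ranges and masks", {
  cfg <- quick_cfg()
  set.seed(3)
  gt <- make_ground_truth(32, 32, cfg)
  expect_true(all(gt$tau[gt$mask] >= 0.6 & gt$tau[gt$mask] <= 2))
  expect_true(all(gt$amplitude[gt$mask] >= 20 & gt$amplitude[gt$mask] <= 100))
  expect_true(all(gt$tau[!gt$mask] == 0))
  expect_true(all(gt$amplitude[!gt$mask] == 0))

  # constant map on a full-foreground mask with a degenerate range
  cfg2 <- pixel_cfg(1)
  cfg2$mask <- matrix(TRUE, 4, 4)
  set.seed(4)
  gt2 <- make_ground_truth(4, 4, cfg2)
  expect_equal(gt2$tau, matrix(1, 4, 4))

  # determinism under a fixed seed
  set.seed(5); a <- make_ground_truth(16, 16, cfg)
  set.seed(5); b <- make_ground_truth(16, 16, cfg)
  expect_identical(a, b)

  cfg3 <- quick_cfg(mask_source = "user_supplied",
                    mask = matrix(FALSE, 4, 4))
  expect_warning(make_ground_truth(4, 4, cfg3), "all-background")
})

test_that("noiseless image generation composes the scalar pipeline", {
  cfg <- pixel_cfg(1.3)
  set.seed(9)
  im <- simulate_image(cfg, 1, 1, noise = FALSE)
  tr <- simulate_decay(1.3, 1, irf_params(cfg$irf_t0, im$irf$fwhm[1, 1],
                                          cfg$irf_order), cfg$grid)
  gates <- sample_gates(tr, find_peak(tr), cfg$gate_spacing)
  expect_equal(as.numeric(im$gates[1, 1, ]), gates, tolerance = 1e-12)
})

test_that("datasets are bit-reproducible under a fixed master seed", {
  cfg <- quick_cfg(seed = 77)
  d1 <- generate_dataset(cfg, 3, 16, 16)
  d2 <- generate_dataset(cfg, 3, 16, 16)
  expect_identical(d1$gates, d2$gates)
  expect_identical(d1$tau, d2$tau)
  expect_identical(d1$snr, d2$snr)

  # foreground gate vectors are max-normalized with the peak first
  mx <- apply(d1$gates, c(1, 2, 4), max)
  expect_true(all(abs(mx[d1$mask] - 1) < 1e-12))
  first <- d1$gates[, , 1, ][d1$mask]
  expect_true(all(first == 1))
  # background pixels are exactly zero at the default background level
  expect_true(all(d1$gates[, , 1, ][!d1$mask] == 0))
})

test_that("procedural digit masks are non-trivial connected strokes", {
  set.seed(21)
  m <- digit_mask(64, 64)
  frac <- mean(m)
  expect_gt(frac, 0.01)
  expect_lt(frac, 0.6)
})
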