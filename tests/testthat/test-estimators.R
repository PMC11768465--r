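test_that("re-convolution fitting inverts the simulator on noiseless traces", {
  g <- time_grid(0, 0.05, 600L)
  set.seed(13)
  for (i in 1:5) {
    tau <- runif(1, 0.6, 2)
    fwhm <- runif(1, 4, 4.5)
    amp <- runif(1, 20, 100)
    tr <- simulate_decay(tau, amp, irf_params(10, fwhm, 4), g)
    f <- reconvolution_fit(tr, irf_params(10, fwhm, 4))
    expect_true(f$converged)
    expect_lt(abs(f$tau - tau) / tau, 1e-3)
    expect_lt(abs(f$amplitude - amp) / amp, 1e-2)
  }
})

test_that("re-convolution fit started at the truth converges immediately", {
  g <- time_grid(0, 0.05, 600L)
  tr <- simulate_decay(1.2, 60, irf_params(10, 4.2, 4), g)
  f <- reconvolution_fit(tr, irf_params(10, 4.2, 4),
                         init = list(tau = 1.2, amplitude = 60, offset = 0))
  expect_true(f$converged)
  expect_lte(f$n_iterations, 5L)
  expect_lt(f$residual_norm, 1e-6 * max(tr$values))
})

test_that("re-convolution RMSE decreases as SNR doubles", {
  g <- time_grid(0, 0.05, 600L)
  p <- irf_params(10, 4.2, 4)
  set.seed(17)
  rmse_at <- function(amp, n_mc = 40L) {
    errs <- vapply(seq_len(n_mc), function(i) {
      tr <- add_poisson_noise(simulate_decay(1.2, amp, p, g))
      reconvolution_fit(tr, p)$tau - 1.2
    }, numeric(1))
    sqrt(mean(errs^2))
  }
  lo <- rmse_at(5)
  hi <- rmse_at(40)
  expect_lt(hi, lo)
})

test_that("tail fitting is exact on geometric gate vectors and flags degenerate input", {
  r <- exp(-1 / 1.5)
  f <- tail_fit(r^(0:5), gate_spacing = 1)
  expect_equal(f$tau, 1.5, tolerance = 1e-9)
  expect_true(f$converged)

  fl <- tail_fit(r^(0:5), gate_spacing = 1, log_linear = TRUE)
  expect_equal(fl$tau, 1.5, tolerance = 1e-12)

  fc <- tail_fit(rep(1, 6), gate_spacing = 1)
  expect_false(fc$converged)
  expect_true(is.na(fc$tau))

  fs <- tail_fit(c(1, 0.5, 0, 0, 0, 0), gate_spacing = 1)
  expect_false(fs$converged)  # fewer than 3 positive samples
})

test_that("tail fitting on IRF-convolved gates is biased upward", {
  cfg <- pixel_cfg(1)
  set.seed(31)
  im <- simulate_image(cfg, 1, 1, noise = FALSE)
  f <- tail_fit(as.numeric(im$gates[1, 1, ]), cfg$gate_spacing)
  expect_gt(f$tau, 1)  # broad gate inflates the apparent lifetime
})

test_that("RLD reproduces its closed form and flags non-decaying gates", {
  expect_equal(rld(c(100, 100 / exp(1)), 1)$tau, 1)
  expect_false(rld(c(5, 5), 1)$converged)
  expect_false(rld(c(0, 1), 1)$converged)
  # on IRF-convolved gates the two-point estimate deviates from the truth
  cfg <- pixel_cfg(1)
  set.seed(33)
  im <- simulate_image(cfg, 1, 1, noise = FALSE)
  est <- rld(as.numeric(im$gates[1, 1, ]), cfg$gate_spacing)$tau
  expect_gt(abs(est - 1), 0.1)
})

test_that("phasor matches the mono-exponential closed form and the semicircle", {
  # omega * tau = 1: g = s = 1/2 in the continuous limit
  tt <- seq(0, 200, by = 0.001)
  ph <- phasor(exp(-tt), omega = 1, t = tt)
  expect_equal(ph$g, 0.5, tolerance = 1e-3)
  expect_equal(ph$s, 0.5, tolerance = 1e-3)
  expect_equal(ph$tau, 1, tolerance = 2e-3)
  # universal semicircle over random lifetimes
  for (tau in c(0.3, 1, 2.7)) {
    p <- phasor(exp(-tt / tau), omega = 0.8, t = tt)
    expect_lt(abs((p$g - 0.5)^2 + p$s^2 - 0.25), 1e-3)
  }
})

test_that("phasor of a uniform trace matches the analytic Fourier coefficients", {
  n <- 2000L
  tt <- seq(0, 10, length.out = n)
  w <- 2 * pi / 10
  p <- phasor(rep(3, n), omega = w, t = tt)
  # discrete sums of cos/sin over a full period, computed independently
  expect_equal(p$g, mean(cos(w * tt)), tolerance = 1e-12)
  expect_equal(p$s, mean(sin(w * tt)), tolerance = 1e-12)
})

test_that("a timing shift changes the phasor lifetime estimate", {
  g <- time_grid(0, 0.05, 1000L)
  p <- irf_params(10, 4.2, 4)
  t0 <- phasor(simulate_decay(1.2, 1, p, g))$tau
  p_sh <- irf_params(10.5, 4.2, 4)
  t1 <- phasor(simulate_decay(1.2, 1, p_sh, g))$tau
  expect_gt(abs(t1 - t0), 0.05)
})

test_that("imagewise fitting handles constant scenes, matches a direct summary, and flags empty input", {
  cfg <- pixel_cfg(1.4)
  cfg$mask <- matrix(TRUE, 4, 4)
  cfg$fwhm_range <- c(4.2, 4.2)
  set.seed(41)
  im <- simulate_image(cfg, 4, 4, noise = FALSE)
  map <- fit_image(im$gates, "tail")
  expect_true(all(map$valid))
  s <- summarize_map(map)
  expect_equal(s$sd_tau, 0, tolerance = 1e-6)

  # mean +/- SD matches a direct per-pixel recomputation
  set.seed(42)
  im2 <- simulate_image(quick_cfg(), 8, 8, noise = TRUE)
  map2 <- suppressWarnings(fit_image(im2$gates, "rld"))
  if (any(map2$valid)) {
    v <- map2$tau[map2$valid]
    s2 <- summarize_map(map2)
    expect_equal(s2$mean_tau, sum(v) / length(v))
    expect_equal(s2$sd_tau, sqrt(sum((v - mean(v))^2) / length(v)))
    expect_equal(s2$n, length(v))
  }

  empty <- gated_stack(array(0, c(2, 2, 6)), 1)
  expect_warning(m0 <- fit_image(empty, "tail"), "no valid")
  expect_true(all(!m0$valid))
})

test_that("imagewise re-convolution fitting recovers a noiseless dense stack", {
  cfg <- pixel_cfg(1.1)
  cfg$mask <- matrix(TRUE, 2, 2)
  set.seed(43)
  grid <- cfg$grid
  field <- irf_field(2, 2, cfg)
  stack <- array(0, c(2, 2, grid$n_bins))
  for (i in 1:2) for (j in 1:2)
    stack[i, j, ] <- simulate_decay(1.1, 50,
                                    irf_params(cfg$irf_t0, field$fwhm[i, j],
                                               cfg$irf_order), grid)$values
  map <- fit_image(stack, "reconv", irf = field, grid = grid)
  expect_true(all(map$valid))
  expect_equal(as.numeric(map$tau), rep(1.1, 4), tolerance = 1e-3)
})
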