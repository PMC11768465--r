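test_that("super-Gaussian IRF peaks at 1, is symmetric, and hits 0.5 at half width", {
  expect_equal(super_gaussian_irf(10, 10, 4, 4), 1.0)
  # half-maximum identity over random parameters
  set.seed(42)
  fwhm <- runif(1000, 0.5, 8)
  ord <- sample(1:6, 1000, replace = TRUE)
  t0 <- runif(1000, -5, 25)
  for (side in c(-1, 1)) {
    v <- vapply(seq_len(1000), function(i)
      super_gaussian_irf(t0[i] + side * fwhm[i] / 2, t0[i], fwhm[i],
                         ord[i]), numeric(1))
    expect_lt(max(abs(v - 0.5)), 1e-12)
  }
  # symmetry about t0
  d <- runif(200, 0, 6)
  expect_equal(super_gaussian_irf(10 + d, 10, 4.2, 4),
               super_gaussian_irf(10 - d, 10, 4.2, 4))
})

test_that("IRF tail value matches direct evaluation of the adopted form", {
  # t = t0 + FWHM, FWHM = 4, N = 4: exponent is -2 * 2^8 * (0.5 * ln 2)
  expect_equal(super_gaussian_irf(14, 10, 4, 4),
               exp(-2 * 2^8 * 0.5 * log(2)))
})

test_that("IRF rejects non-finite times and bad parameters", {
  expect_error(super_gaussian_irf(NaN, 10, 4, 4), "finite")
  expect_error(super_gaussian_irf(Inf, 10, 4, 4), "finite")
  expect_error(irf_params(10, -1, 4), "positive")
  expect_error(irf_params(10, 4, 0), ">= 1")
})

test_that("IRF field draws one FWHM per pixel from the configured range", {
  cfg <- flim_sim_config()
  set.seed(7)
  f <- irf_field(128, 128, cfg)
  expect_equal(length(f$fwhm), 16384L)  # one IRF per pixel at 128 x 128
  expect_true(all(f$fwhm >= 4 & f$fwhm <= 4.5))
  expect_equal(f$order, 4L)

  f1 <- irf_field(1, 1, cfg)
  expect_length(f1$fwhm, 1L)
  expect_true(f1$fwhm >= 4 && f1$fwhm <= 4.5)

  cfg$fwhm_range <- c(4, 4)  # degenerate range
  fd <- irf_field(3, 3, cfg)
  expect_true(all(fd$fwhm == 4))

  cfg$fwhm_range <- numeric(0)
  expect_error(irf_field(2, 2, cfg), "fwhm_range")
  expect_error(irf_field(0, 4, cfg), ">= 1")
})
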