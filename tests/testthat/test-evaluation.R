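test_that("the oracle estimator has zero error in every protocol", {
  cfg <- quick_cfg(seed = 61)
  r <- mae_by_snr("oracle", cfg, n_subsets = 2L, images_per_subset = 2L,
                  height = 12L, width = 12L)
  expect_true(all(r$mae == 0))

  sw <- tau_sweep("oracle", quick_cfg(seed = 62), n_images = 1L,
                  amplitudes = c(20, 50), height = 12L, width = 12L)
  expect_true(all(sw$mae[sw$n > 0] == 0))
})

test_that("SNR targeting reaches the requested photon counts", {
  cfg <- quick_cfg(seed = 63)
  r <- mae_by_snr("oracle", cfg, n_subsets = 3L, images_per_subset = 2L,
                  snr_db_range = c(12, 24), height = 12L, width = 12L)
  expect_equal(r$snr_db_achieved, r$snr_db, tolerance = 0.05)
})

test_that("summary statistics follow the population-SD convention", {
  m <- lifetime_map(matrix(c(1, 2), 1), matrix(TRUE, 1, 2))
  s <- summarize_map(m)
  expect_equal(s$mean_tau, 1.5)
  expect_equal(s$sd_tau, 0.5)
  expect_equal(s$n, 2L)

  cm <- lifetime_map(matrix(1.18, 3, 3), matrix(TRUE, 3, 3))
  sc <- summarize_map(cm)
  expect_equal(sc$mean_tau, 1.18)
  expect_equal(sc$sd_tau, 0)

  none <- lifetime_map(matrix(1, 2, 2), matrix(FALSE, 2, 2))
  expect_warning(s0 <- summarize_map(none), "no valid")
  expect_equal(s0$n, 0L)
})

test_that("histogram overlays conserve counts and match on identical maps", {
  set.seed(64)
  tau <- matrix(runif(100, 0.6, 2), 10)
  m1 <- lifetime_map(tau, matrix(TRUE, 10, 10), "a")
  m2 <- lifetime_map(tau, matrix(TRUE, 10, 10), "b")
  h <- histogram_compare(list(a = m1, b = m2), breaks = 12L)
  a <- h[h$method == "a", ]; b <- h[h$method == "b", ]
  expect_equal(sum(a$count), 100L)
  expect_equal(a$count, b$count)
  expect_equal(a$density, b$density)
})

test_that("re-convolution and tail-fit histograms of one high-SNR image share their mode", {
  cfg <- quick_cfg(seed = 65, tau_range = c(1.2, 1.2))
  set.seed(65)
  im <- simulate_image(cfg, 10, 10, noise = TRUE, snr_target = 200)
  grid <- cfg$grid
  # dense-stack re-convolution reference on a subsample of pixels
  fg <- which(im$truth$mask, arr.ind = TRUE)
  tail_map <- suppressWarnings(fit_image(im$gates, "tail"))
  h <- histogram_compare(list(tail = tail_map),
                         breaks = seq(0, 4, by = 0.25))
  tl <- h[h$method == "tail", ]
  mode_tail <- tl$bin_mid[which.max(tl$count)]
  # the tail fit is biased upward but its mode stays within a bin or two
  expect_lt(abs(mode_tail - 1.2), 1)
})

test_that("t-SNE embeds with one point per voxel and a positive lifetime gradient", {
  set.seed(66)
  n <- 120L
  tau <- runif(n, 0.6, 2)
  # structured synthetic features: smooth functions of tau plus noise
  feats <- cbind(tau, tau^2, exp(-tau), sqrt(tau)) +
    matrix(rnorm(n * 4, sd = 0.01), n)
  emb <- tsne_embed(feats, tau = tau, n_components = 3L, seed = 1,
                    max_iter = 250L)
  expect_equal(dim(emb$Y), c(n, 3L))
  expect_gt(emb$neighbor_rank_cor, 0.5)

  expect_error(tsne_embed(feats[1:10, ], tau = tau[1:10]), "at least 50")
  expect_warning(tsne_embed(matrix(1, 60, 4), max_iter = 5L), "degenerate")
})

test_that("zero offsets leave every estimator unchanged", {
  cfg <- quick_cfg(seed = 67)
  res <- offset_robustness(
    list(tail = function(s, t) fit_image(s, "tail"),
         rld = function(s, t) suppressWarnings(fit_image(s, "rld"))),
    cfg, tau = 1.2, max_offset = 0, height = 6L, width = 6L)
  expect_true(all(res$shift == 0))
})

test_that("timing offsets shift the dense phasor but not peak-aligned estimators", {
  cfg <- quick_cfg(seed = 68)
  res <- offset_robustness(
    list(tail = function(s, t) fit_image(s, "tail"),
         phasor_fixed = "phasor_fixed",
         rld_fixed = "rld_fixed"),
    cfg, tau = 1.2, max_offset = 2, height = 6L, width = 6L)
  expect_equal(res$shift[res$method == "tail"], 0)
  expect_gt(abs(res$shift[res$method == "phasor_fixed"]), 0.05)
  expect_gt(abs(res$shift[res$method == "rld_fixed"]), 0.05)
})
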