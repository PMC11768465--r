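test_that("the default network reports the reference parameter count", {
  m <- build_fltcnn(seed = 1)
  expect_identical(count_parameters(m), 71461)
  expect_identical(count_parameters(freeze_fltcnn(m)), 0)
})

test_that("a lone temporal convolution has the closed-form parameter count", {
  set.seed(1)
  stem <- flimgate:::nn_convd(6L, 1L, 64L, 6L)
  expect_identical(flimgate:::nn_count_params(stem), 6 * 64 + 64)  # 448
})

test_that("the network is fully convolutional over image size", {
  m <- build_fltcnn(seed = 2)
  for (hw in list(c(8L, 8L), c(5L, 11L))) {
    stack <- gated_stack(array(runif(prod(hw) * 6), c(hw, 6L)), 1)
    out <- predict(m, stack)
    expect_equal(dim(out$tau), hw)
  }
  expect_error(predict(m, array(runif(4 * 4 * 5), c(4, 4, 5))), "5 gates")
})

test_that("prediction is equivariant under pixel permutations", {
  m <- build_fltcnn(seed = 3)
  set.seed(5)
  X <- matrix(runif(200 * 6), 200, 6)
  p <- sample.int(200)
  expect_identical(predict(m, X)[p], predict(m, X[p, ]))
})

test_that("predicted lifetimes are non-negative under the ReLU head", {
  m <- build_fltcnn(seed = 4)
  set.seed(6)
  expect_true(all(predict(m, matrix(runif(600), 100, 6)) >= 0))
})

test_that("features come from the pre-head block with the configured width", {
  m <- build_fltcnn(seed = 5)
  set.seed(7)
  X <- matrix(runif(1000 * 6), 1000, 6)
  ft <- extract_features(m, X)
  expect_equal(dim(ft), c(1000L, 32L))
  # identical inputs give identical features
  X2 <- X[c(1, 1, 2), ]
  f2 <- extract_features(m, X2)
  expect_identical(f2[1, ], f2[2, ])
})

test_that("the batch loss matches its per-element recomputation", {
  # two images with residual norms^2 of 1 and 4 -> loss 2.5
  expect_equal(loss_batch_mse(c(1, 0, 2, 0), c(0, 0, 0, 0), 2), 2.5)
  # perfect prediction -> zero
  expect_equal(loss_batch_mse(c(1.2, 0.8), c(1.2, 0.8), 2), 0)
  # against an independent elementwise recomputation on a random batch
  set.seed(8)
  pred <- runif(64); truth <- runif(64)
  manual <- sum(vapply(0:3, function(i)
    sum((pred[i * 16 + 1:16] - truth[i * 16 + 1:16])^2), numeric(1))) / 4
  expect_equal(loss_batch_mse(pred, truth, 4), manual, tolerance = 1e-6)
})

test_that("backpropagation matches finite differences on a tiny network", {
  cfg <- fltcnn_config(downsample_filters = c(5L, 3L, 2L, 1L),
                       output_activation = "linear")
  m <- build_fltcnn(cfg, seed = 2)
  set.seed(3)
  X <- matrix(runif(7 * 6), 7, 6)
  y <- runif(7)
  loss_of <- function(model)
    sum((flimgate:::fltcnn_forward(model, X, training = TRUE)$pred - y)^2)
  fw <- flimgate:::fltcnn_forward(m, X, training = TRUE)
  dpred <- matrix(2 * (fw$pred - y), ncol = 1)
  hb <- flimgate:::nn_backward(m$head, fw$hcache, dpred)
  fb <- flimgate:::nn_backward(m$feature, fw$fcache, hb$dX)

  perturb <- function(part, path, pn, ii, h) {
    mm <- m
    rec <- function(node, p) {
      if (length(p) == 0L) { node[[pn]][ii] <- node[[pn]][ii] + h; return(node) }
      key <- p[[1]]
      if (is.character(key)) node[[key]] <- rec(node[[key]], p[-1])
      else node$nodes[[key]] <- rec(node$nodes[[key]], p[-1])
      node
    }
    mm[[part]] <- rec(mm[[part]], path)
    mm
  }
  check <- function(node, grads, path, part) {
    if (node$type %in% c("dense", "pointwise", "convd", "bn")) {
      for (pn in intersect(c("W", "b", "gamma", "beta"), names(node))) {
        g <- grads[[pn]]
        for (ii in sample(length(g), min(2L, length(g)))) {
          h <- 1e-5
          num <- (loss_of(perturb(part, path, pn, ii, h)) -
                    loss_of(perturb(part, path, pn, ii, -h))) / (2 * h)
          expect_equal(g[ii], num, tolerance = 1e-4)
        }
      }
    } else if (node$type == "seq") {
      for (i in seq_along(node$nodes))
        if (!is.null(grads[[i]]))
          check(node$nodes[[i]], grads[[i]], c(path, i), part)
    } else if (node$type == "res") {
      check(node$main, grads$main, c(path, "main"), part)
      if (!is.null(node$skip))
        check(node$skip, grads$skip, c(path, "skip"), part)
    }
  }
  set.seed(4)
  check(m$feature, fb$grads, list(), "feature")
  check(m$head, hb$grads, list(), "head")
})

test_that("a short training run reduces the validation error", {
  ds <- generate_dataset(quick_cfg(seed = 55), 30, 16, 16)
  m <- build_fltcnn(seed = 9)
  tc <- fltcnn_training_config(lr_initial = 1e-3, batch_size = 8L,
                               max_epochs = 6L, seed = 10)
  m2 <- fltcnn_train(m, ds, tc)
  h <- m2$history$epochs
  expect_lt(h$val_mae[m2$history$best_epoch], h$val_mae[1])
  expect_true(m2$meta$trained)
  expect_equal(m2$meta$gate_spacing, 1)
  # gate-spacing mismatch at prediction time is an error
  st <- gated_stack(ds$gates[, , , 1], 0.5)
  expect_error(predict(m2, st), "gate spacing")
})

test_that("training aborts with a diagnostic on divergence", {
  ds <- generate_dataset(quick_cfg(seed = 56), 6, 8, 8)
  m <- build_fltcnn(fltcnn_config(output_activation = "linear"), seed = 11)
  tc <- fltcnn_training_config(lr_initial = 1e200, batch_size = 3L,
                               max_epochs = 3L, seed = 12)
  expect_error(fltcnn_train(m, ds, tc), "diverged|lr")
})
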