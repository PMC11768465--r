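# Internal per-pixel network engine.
#
# Every kernel in the lifetime network is 1x1 in the two spatial
# dimensions, so the whole network is exactly a per-pixel function of the
# gate vector.  Activations are therefore stored as plain matrices with
# one row per pixel.  A stage that still carries a depth (time) axis of
# size d with C channels uses N x (d*C) matrices whose columns are grouped
# in d depth blocks of C channels ("depth-block-major"); 2D stages are the
# special case d = 1.
#
# Node types: dense, convd (1D convolution along the depth axis, "same"
# zero padding), pointwise (per-depth-position dense map, i.e. a 1x1x1
# convolution), bn (batch normalization over N*d samples per channel),
# relu, seq (sequence), res (residual block: main path + additive skip
# with optional projection, ReLU after the addition).
#
# nn_forward() returns the output, a cache for the backward pass, and the
# (possibly updated: BN running statistics) node.  nn_backward() returns
# the input gradient and a parameter-gradient structure mirroring the
# node.  nn_update() applies RMSprop.

glorot <- function(nr, nc, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

nn_dense <- function(cin, cout) {
  list(type = "dense", cin = cin, cout = cout,
       W = glorot(cin, cout, cin, cout), b = numeric(cout),
       trainable = TRUE)
}

nn_convd <- function(k, cin, cout, d) {
  pad_left <- (k - 1L) %/% 2L
  blocks <- list()
  for (dp in seq_len(d)) for (i in seq_len(d)) {
    j <- i - dp + pad_left + 1L
    if (j >= 1L && j <= k)
      blocks[[length(blocks) + 1L]] <- c(dp = dp, i = i, j = j)
  }
  list(type = "convd", k = k, cin = cin, cout = cout, d = d,
       blocks = blocks,
       W = glorot(k * cin, cout, k * cin, k * cout), b = numeric(cout),
       trainable = TRUE)
}

nn_pointwise <- function(cin, cout, d) {
  list(type = "pointwise", cin = cin, cout = cout, d = d,
       W = glorot(cin, cout, cin, cout), b = numeric(cout),
       trainable = TRUE)
}

nn_bn <- function(C, d = 1L, momentum = 0.9, eps = 1e-3) {
  list(type = "bn", C = C, d = d, momentum = momentum, eps = eps,
       gamma = rep(1, C), beta = numeric(C),
       rmean = numeric(C), rvar = rep(1, C),
       trainable = TRUE)
}

nn_relu <- function() list(type = "relu")

nn_seq <- function(nodes) list(type = "seq", nodes = nodes)

nn_res <- function(main, skip = NULL)
  list(type = "res", main = main, skip = skip)

# per-channel column sum helper: M has d blocks of C columns
ch_sum <- function(M, C, d) {
  cs <- colSums(M)
  if (d == 1L) cs else rowSums(matrix(cs, C, d))
}

convd_wall <- function(node) {
  W_all <- matrix(0, node$d * node$cin, node$d * node$cout)
  for (bl in node$blocks) {
    ri <- (bl[["i"]] - 1L) * node$cin + seq_len(node$cin)
    co <- (bl[["dp"]] - 1L) * node$cout + seq_len(node$cout)
    rj <- (bl[["j"]] - 1L) * node$cin + seq_len(node$cin)
    W_all[ri, co] <- node$W[rj, ]
  }
  W_all
}

nn_forward <- function(node, X, training = FALSE, fast = FALSE) {
  blas <- training || fast
  switch(node$type,
    dense = {
      Y <- if (blas) X %*% node$W else gemm_det_cpp(X, node$W)
      add_bias_cpp(Y, node$b)
      list(Y = Y, cache = list(X = X), node = node)
    },
    pointwise = {
      Y <- matrix(0, nrow(X), node$d * node$cout)
      for (dp in seq_len(node$d)) {
        bi <- (dp - 1L) * node$cin + seq_len(node$cin)
        bo <- (dp - 1L) * node$cout + seq_len(node$cout)
        Xb <- X[, bi, drop = FALSE]
        Yb <- if (blas) Xb %*% node$W else gemm_det_cpp(Xb, node$W)
        add_bias_cpp(Yb, node$b)
        Y[, bo] <- Yb
      }
      list(Y = Y, cache = list(X = X), node = node)
    },
    convd = {
      W_all <- convd_wall(node)
      Y <- if (blas) X %*% W_all else gemm_det_cpp(X, W_all)
      add_bias_cpp(Y, node$b)
      list(Y = Y, cache = list(X = X, W_all = W_all), node = node)
    },
    bn = {
      C <- node$C; d <- node$d
      if (training) {
        st <- bn_stats_cpp(X, C, d)
        node$rmean <- node$momentum * node$rmean +
          (1 - node$momentum) * st$mu
        node$rvar <- node$momentum * node$rvar + (1 - node$momentum) * st$va
        sdv <- sqrt(st$va + node$eps)
        r <- bn_fwd_cpp(X, st$mu, sdv, node$gamma, node$beta, C)
        list(Y = r$Y, cache = list(xhat = r$xhat, sdv = sdv), node = node)
      } else {
        # inference: affine in the running statistics, no backward cache
        sdv <- sqrt(node$rvar + node$eps)
        a <- node$gamma / sdv
        Y <- bn_infer_cpp(X, a, node$beta - a * node$rmean, C)
        list(Y = Y, cache = NULL, node = node)
      }
    },
    relu = {
      Y <- relu_fwd_cpp(X)
      list(Y = Y, cache = list(Y = Y), node = node)
    },
    seq = {
      caches <- vector("list", length(node$nodes))
      for (i in seq_along(node$nodes)) {
        r <- nn_forward(node$nodes[[i]], X, training, fast)
        X <- r$Y; caches[[i]] <- r$cache; node$nodes[[i]] <- r$node
      }
      list(Y = X, cache = caches, node = node)
    },
    res = {
      mr <- nn_forward(node$main, X, training, fast)
      node$main <- mr$node
      if (is.null(node$skip)) {
        Ys <- X; sc <- NULL
      } else {
        sr <- nn_forward(node$skip, X, training, fast)
        Ys <- sr$Y; sc <- sr$cache; node$skip <- sr$node
      }
      Y <- add_relu_cpp(mr$Y, Ys)
      list(Y = Y, cache = list(main = mr$cache, skip = sc, Y = Y),
           node = node)
    },
    stop("unknown node type: ", node$type))
}

nn_backward <- function(node, cache, dY) {
  switch(node$type,
    dense = {
      list(dX = dY %*% t(node$W),
           grads = list(W = crossprod(cache$X, dY), b = colSums(dY)))
    },
    pointwise = {
      dX <- matrix(0, nrow(dY), node$d * node$cin)
      dW <- matrix(0, node$cin, node$cout)
      db <- numeric(node$cout)
      for (dp in seq_len(node$d)) {
        bi <- (dp - 1L) * node$cin + seq_len(node$cin)
        bo <- (dp - 1L) * node$cout + seq_len(node$cout)
        dYb <- dY[, bo, drop = FALSE]
        dX[, bi] <- dYb %*% t(node$W)
        dW <- dW + crossprod(cache$X[, bi, drop = FALSE], dYb)
        db <- db + colSums(dYb)
      }
      list(dX = dX, grads = list(W = dW, b = db))
    },
    convd = {
      dX <- dY %*% t(cache$W_all)
      dW_all <- crossprod(cache$X, dY)
      dW <- matrix(0, node$k * node$cin, node$cout)
      for (bl in node$blocks) {
        ri <- (bl[["i"]] - 1L) * node$cin + seq_len(node$cin)
        co <- (bl[["dp"]] - 1L) * node$cout + seq_len(node$cout)
        rj <- (bl[["j"]] - 1L) * node$cin + seq_len(node$cin)
        dW[rj, ] <- dW[rj, ] + dW_all[ri, co]
      }
      db <- rowSums(matrix(colSums(dY), node$cout, node$d))
      list(dX = dX, grads = list(W = dW, b = db))
    },
    bn = {
      r <- bn_bwd_cpp(dY, cache$xhat, node$gamma, cache$sdv,
                      node$C, node$d)
      list(dX = r$dX, grads = list(gamma = r$dgamma, beta = r$dbeta))
    },
    relu = list(dX = relu_bwd_cpp(dY, cache$Y), grads = NULL),
    seq = {
      n <- length(node$nodes)
      grads <- vector("list", n)
      for (i in rev(seq_len(n))) {
        r <- nn_backward(node$nodes[[i]], cache[[i]], dY)
        dY <- r$dX
        grads[i] <- list(r$grads)  # keep NULL placeholders for relu nodes
      }
      list(dX = dY, grads = grads)
    },
    res = {
      dZ <- relu_bwd_cpp(dY, cache$Y)
      mr <- nn_backward(node$main, cache$main, dZ)
      if (is.null(node$skip)) {
        dXs <- dZ; sg <- NULL
      } else {
        sr <- nn_backward(node$skip, cache$skip, dZ)
        dXs <- sr$dX; sg <- sr$grads
      }
      list(dX = mr$dX + dXs, grads = list(main = mr$grads, skip = sg))
    },
    stop("unknown node type: ", node$type))
}

nn_param_names <- function(node)
  intersect(c("W", "b", "gamma", "beta"), names(node))

# RMSprop: v <- rho v + (1 - rho) g^2 ; p <- p - lr g / (sqrt(v) + eps)
nn_update <- function(node, grads, state, lr, rho = 0.9, eps = 1e-7) {
  if (node$type %in% c("dense", "pointwise", "convd", "bn")) {
    if (!isTRUE(node$trainable)) return(list(node = node, state = state))
    for (pn in nn_param_names(node)) {
      g <- grads[[pn]]
      v <- state[[pn]]
      if (is.null(v)) v <- g * 0
      v <- rho * v + (1 - rho) * g^2
      node[[pn]] <- node[[pn]] - lr * g / (sqrt(v) + eps)
      state[[pn]] <- v
    }
  } else if (node$type == "seq") {
    if (is.null(state)) state <- vector("list", length(node$nodes))
    for (i in seq_along(node$nodes)) {
      if (is.null(grads[[i]]) && !(node$nodes[[i]]$type %in% c("seq", "res")))
        next
      r <- nn_update(node$nodes[[i]], grads[[i]], state[[i]], lr, rho, eps)
      node$nodes[[i]] <- r$node; state[[i]] <- r$state
    }
  } else if (node$type == "res") {
    if (is.null(state)) state <- list(main = NULL, skip = NULL)
    r <- nn_update(node$main, grads$main, state$main, lr, rho, eps)
    node$main <- r$node; state$main <- r$state
    if (!is.null(node$skip)) {
      r <- nn_update(node$skip, grads$skip, state$skip, lr, rho, eps)
      node$skip <- r$node; state$skip <- r$state
    }
  }
  list(node = node, state = state)
}

nn_count_params <- function(node) {
  switch(node$type,
    seq = sum(vapply(node$nodes, nn_count_params, numeric(1))),
    res = nn_count_params(node$main) +
      (if (is.null(node$skip)) 0 else nn_count_params(node$skip)),
    relu = 0,
    {
      if (!isTRUE(node$trainable)) return(0)
      sum(vapply(nn_param_names(node),
                 function(pn) length(node[[pn]]), numeric(1)))
    })
}

nn_freeze <- function(node) {
  if (node$type == "seq") {
    node$nodes <- lapply(node$nodes, nn_freeze)
  } else if (node$type == "res") {
    node$main <- nn_freeze(node$main)
    if (!is.null(node$skip)) node$skip <- nn_freeze(node$skip)
  } else if (!is.null(node$trainable)) {
    node$trainable <- FALSE
  }
  node
}
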