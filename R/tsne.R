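#' t-SNE embedding of per-pixel features
#'
#' Embeds per-pixel feature vectors (from [extract_features()]) into a
#' low-dimensional space with t-distributed stochastic neighbor embedding
#' (exact affinities with per-point perplexity calibration, early
#' exaggeration, momentum gradient descent).  Because visual cluster
#' structure is not testable, a quantitative companion statistic is
#' returned: the Spearman rank correlation between each point's lifetime
#' and the lifetime of its nearest embedding-space neighbor -- positive
#' when the embedding orders features by lifetime.
#'
#' @param features `n x p` matrix of feature vectors (`n >= 50`).
#' @param tau optional ground-truth lifetimes (length `n`) used for the
#'   color mapping and the neighbor statistic.
#' @param n_components embedding dimensionality.
#' @param perplexity target perplexity of the conditional affinities.
#' @param max_iter gradient-descent iterations.
#' @param seed RNG seed for the initialization.
#' @return A list of class `"tsne_embedding"`: `Y` (`n x n_components`
#'   coordinates), `tau`, `neighbor_rank_cor` (`NA` without `tau`).
#' @export
tsne_embed <- function(features, tau = NULL, n_components = 3L,
                       perplexity = 30, max_iter = 400L, seed = NULL) {
  stopifnot(is.matrix(features))
  n <- nrow(features)
  if (n < 50L) stop("t-SNE embedding requires at least 50 feature vectors")
  if (!is.null(tau) && length(tau) != n)
    stop("'tau' must have one value per feature vector")
  if (stats::var(as.numeric(features)) == 0)
    warning("degenerate (all-identical) features")
  perplexity <- min(perplexity, (n - 1) / 3)
  if (!is.null(seed)) set.seed(seed)

  D2 <- as.matrix(stats::dist(features))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    beta <- 1
    lo <- -Inf; hi <- Inf
    for (iter in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) { p[] <- 1 / length(p); sp <- 1 }
      p <- p / sp
      h <- -sum(p[p > 0] * log(p[p > 0]))
      if (abs(h - logU) < 1e-5) break
      if (h > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P[P < 1e-12] <- 1e-12

  Y <- matrix(rnorm(n * n_components, sd = 1e-4), n, n_components)
  G <- matrix(0, n, n_components)
  eta <- 200; momentum <- 0.5
  for (it in seq_len(max_iter)) {
    ex <- if (it <= 100L) 12 else 1   # early exaggeration
    if (it == 21L) momentum <- 0.8
    num <- 1 / (1 + as.matrix(stats::dist(Y))^2)
    diag(num) <- 0
    Q <- num / sum(num)
    Q[Q < 1e-12] <- 1e-12
    W <- (ex * P - Q) * num
    grad <- 4 * (diag(rowSums(W)) - W) %*% Y
    G <- momentum * G - eta * grad
    Y <- Y + G
    Y <- sweep(Y, 2L, colMeans(Y))
  }

  nrc <- NA_real_
  if (!is.null(tau)) {
    dY <- as.matrix(stats::dist(Y))
    diag(dY) <- Inf
    nn <- apply(dY, 1L, which.min)
    nrc <- stats::cor(tau, tau[nn], method = "spearman")
  }
  structure(list(Y = Y, tau = tau, neighbor_rank_cor = nrc,
                 perplexity = perplexity),
            class = "tsne_embedding")
}

#' @export
print.tsne_embedding <- function(x, ...) {
  cat(sprintf(
    "<tsne_embedding> %d points in %d-D (perplexity %.1f), neighbor rank cor %s\n",
    nrow(x$Y), ncol(x$Y), x$perplexity,
    if (is.na(x$neighbor_rank_cor)) "NA"
    else sprintf("%.3f", x$neighbor_rank_cor)))
  invisible(x)
}
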