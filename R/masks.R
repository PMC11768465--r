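#' Procedural digit-like foreground masks
#'
#' Spatial supports for the simulator: connected, stroke-like blobs that
#' mimic handwritten digits (curved strokes of a few pixels thickness on an
#' otherwise empty frame).  Only the topology matters downstream -- the
#' masks merely decide which pixels carry a decay -- so a procedural
#' generator is used instead of a scanned-digit database.
#'
#' Each shape is a random quadratic Bezier stroke rasterized onto the grid
#' and dilated to the requested thickness.
#'
#' @param height,width mask dimensions in pixels.
#' @param n_strokes number of strokes; by default 2--4, drawn at random.
#' @param thickness dilation radius in pixels.
#' @return Logical `height x width` matrix, `TRUE` on the foreground.
#' @examples
#' set.seed(1)
#' m <- digit_mask(32, 32)
#' mean(m)
#' @export
digit_mask <- function(height, width, n_strokes = NULL, thickness = 1L) {
  height <- as.integer(height); width <- as.integer(width)
  stopifnot(height >= 1L, width >= 1L)
  if (is.null(n_strokes)) n_strokes <- sample(2:4, 1L)
  mask <- matrix(FALSE, height, width)
  margin <- 0.1
  rpt <- function() c(runif(1, margin, 1 - margin) * height,
                      runif(1, margin, 1 - margin) * width)
  for (k in seq_len(n_strokes)) {
    p0 <- rpt(); p1 <- rpt(); p2 <- rpt()
    tt <- seq(0, 1, length.out = 4L * (height + width))
    ry <- (1 - tt)^2 * p0[1] + 2 * (1 - tt) * tt * p1[1] + tt^2 * p2[1]
    rx <- (1 - tt)^2 * p0[2] + 2 * (1 - tt) * tt * p1[2] + tt^2 * p2[2]
    i <- pmin(pmax(round(ry), 1L), height)
    j <- pmin(pmax(round(rx), 1L), width)
    mask[cbind(i, j)] <- TRUE
  }
  if (thickness > 0L) mask <- dilate_mask(mask, as.integer(thickness))
  mask
}

# square structuring-element dilation by radius r
dilate_mask <- function(mask, r) {
  h <- nrow(mask); w <- ncol(mask)
  out <- mask
  for (di in -r:r) {
    si <- seq_len(h) + di
    ok_i <- si >= 1L & si <= h
    for (dj in -r:r) {
      if (di == 0L && dj == 0L) next
      sj <- seq_len(w) + dj
      ok_j <- sj >= 1L & sj <= w
      out[ok_i, ok_j] <- out[ok_i, ok_j] | mask[si[ok_i], sj[ok_j]]
    }
  }
  out
}

#' Per-pixel ground truth for one synthetic image
#'
#' Draws a foreground mask (digit-like strokes or a user-supplied matrix)
#' and, per foreground pixel, a lifetime `tau ~ U(tau_range)` and amplitude
#' `A ~ U(amp_range)`.  Background pixels have `tau = 0` and
#' `amplitude = 0`.
#'
#' @param height,width image dimensions in pixels.
#' @param cfg a [flim_sim_config()].
#' @return An object of class `"ground_truth_map"`: list with matrices
#'   `tau`, `amplitude` and logical `mask`.
#' @examples
#' set.seed(2)
#' gt <- make_ground_truth(32, 32, flim_sim_config())
#' range(gt$tau[gt$mask])
#' @export
make_ground_truth <- function(height, width, cfg = flim_sim_config()) {
  mask <- switch(cfg$mask_source,
    procedural_digits = digit_mask(height, width),
    user_supplied = {
      m <- cfg$mask
      if (nrow(m) != height || ncol(m) != width)
        stop("user-supplied mask dimensions do not match image size")
      m
    })
  if (!any(mask))
    warning("all-background mask: image contains no decays")
  n_fg <- sum(mask)
  tau <- amp <- matrix(0, height, width)
  tau[mask] <- runif(n_fg, cfg$tau_range[1], cfg$tau_range[2])
  amp[mask] <- runif(n_fg, cfg$amp_range[1], cfg$amp_range[2])
  structure(list(tau = tau, amplitude = amp, mask = mask),
            class = "ground_truth_map")
}

#' @export
print.ground_truth_map <- function(x, ...) {
  cat(sprintf("<ground_truth_map> %d x %d, %d foreground pixels",
              nrow(x$tau), ncol(x$tau), sum(x$mask)))
  if (any(x$mask))
    cat(sprintf(", tau in [%.3f, %.3f] ns", min(x$tau[x$mask]),
                max(x$tau[x$mask])))
  cat("\n")
  invisible(x)
}
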