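#' Dense decay trace
#'
#' A per-bin signal on a [time_grid()], tagged with the noise model that
#' produced it (`"none"` or `"poisson"`).
#'
#' @param values non-negative per-bin intensities, one per grid bin.
#' @param grid the [time_grid()] the values live on.
#' @param noise `"none"` or `"poisson"`.
#' @return An object of class `"dense_trace"`.
#' @export
dense_trace <- function(values, grid, noise = c("none", "poisson")) {
  noise <- match.arg(noise)
  stopifnot(is_time_grid(grid))
  if (!is.numeric(values) || length(values) != grid$n_bins)
    stop("'values' must be numeric with one entry per grid bin")
  if (anyNA(values) || any(!is.finite(values)))
    stop("trace values must be finite")
  structure(list(values = as.numeric(values), grid = grid, noise = noise),
            class = "dense_trace")
}

#' @export
print.dense_trace <- function(x, ...) {
  cat(sprintf("<dense_trace> %d bins, noise = %s, total = %.4g, peak = %.4g\n",
              x$grid$n_bins, x$noise, sum(x$values), max(x$values)))
  invisible(x)
}

# linear (acausal-free) convolution of two equal-length vectors via FFT,
# truncated to the first n bins and scaled by dt:
#   c_k = dt * sum_{i<=k} a_i b_{k-i}
conv_fft <- function(a, b, dt = 1) {
  n <- length(a)
  stopifnot(length(b) == n)
  m <- 2L^ceiling(log2(2L * n))
  ap <- c(a, numeric(m - n)); bp <- c(b, numeric(m - n))
  out <- Re(fft(fft(ap) * fft(bp), inverse = TRUE))[seq_len(n)] / m
  pmax(out * dt, 0)
}

# columnwise FFT convolution of two matrices (n_bins x n_pixels)
conv_fft_mat <- function(A, B, dt = 1) {
  n <- nrow(A)
  m <- 2L^ceiling(log2(2L * n))
  pad <- matrix(0, m - n, ncol(A))
  out <- Re(mvfft(mvfft(rbind(A, pad)) * mvfft(rbind(B, pad)),
                  inverse = TRUE))[seq_len(n), , drop = FALSE] / m
  out[out < 0] <- 0
  out * dt
}

#' Simulate a noiseless IRF-convolved mono-exponential decay
#'
#' Evaluates the causal decay `A * exp(-t / tau)` (zero before the grid
#' origin) and the super-Gaussian IRF on the dense grid, and returns their
#' discrete convolution.  The trace rises to a single peak and then decays.
#'
#' @param tau lifetime (ns), positive.
#' @param amplitude pre-exponential `A` (counts), positive.
#' @param irf an [irf_params()] object.
#' @param grid a [time_grid()].
#' @return A noiseless [dense_trace()].
#' @examples
#' tr <- simulate_decay(1.2, 50, irf_params(10, 4.2, 4), time_grid())
#' which.max(tr$values)
#' @export
simulate_decay <- function(tau, amplitude, irf, grid = time_grid()) {
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0)
    stop("'tau' must be a single positive number")
  if (!is.numeric(amplitude) || length(amplitude) != 1L ||
      !is.finite(amplitude) || amplitude <= 0)
    stop("'amplitude' must be a single positive number")
  irf <- irf_params(irf$t0, irf$fwhm, irf$order)
  stopifnot(is_time_grid(grid))
  decay <- amplitude * exp(-(grid$t - grid$t[1]) / tau)
  kern <- super_gaussian_irf(grid$t, irf$t0, irf$fwhm, irf$order)
  vals <- conv_fft(kern, decay, grid$dt)
  pk <- which.max(vals)
  if (pk >= grid$n_bins)
    stop("grid too short to contain the decay peak; extend 'n_bins'")
  dense_trace(vals, grid, "none")
}

#' Add Poisson noise to a trace
#'
#' Replaces each bin by a Poisson draw whose mean is the bin's expected
#' count plus a constant background mean.
#'
#' @param trace a [dense_trace()] with non-negative values interpreted as
#'   expected counts.
#' @param background constant background mean added to every bin (counts).
#' @return A [dense_trace()] with integer-valued counts, tagged
#'   `"poisson"`.
#' @export
add_poisson_noise <- function(trace, background = 0) {
  stopifnot(inherits(trace, "dense_trace"))
  if (background < 0) stop("'background' must be >= 0")
  lam <- trace$values + background
  if (any(lam < 0)) stop("negative Poisson means")
  dense_trace(as.numeric(rpois(length(lam), lam)), trace$grid, "poisson")
}

#' Signal-to-noise ratio of a decay
#'
#' For Poisson-limited detection the SNR of a decay is the square root of
#' its total photon count, `sqrt(sum(D))`.  `snr_db()` expresses the same
#' quantity in decibels as `20 * log10(SNR) = 10 * log10(total counts)`.
#'
#' @param trace a [dense_trace()] or numeric vector of counts (>= 0).
#' @return `compute_snr()`: the unitless SNR; `snr_db()`: SNR in dB
#'   (`-Inf` for an all-zero trace).
#' @examples
#' compute_snr(c(4, 9, 12))  # 5
#' @export
compute_snr <- function(trace) {
  v <- if (inherits(trace, "dense_trace")) trace$values else trace
  if (any(v < 0)) stop("counts must be >= 0")
  tot <- sum(v)
  if (tot == 0) {
    warning("all-zero trace: SNR is 0")
    return(0)
  }
  sqrt(tot)
}

#' @rdname compute_snr
#' @export
snr_db <- function(trace) {
  s <- compute_snr(trace)
  if (s == 0) return(-Inf)
  20 * log10(s)
}

#' Locate the decay peak
#'
#' Index of the global maximum of the trace; ties are broken by the
#' earliest index.  No sub-bin refinement is attempted.
#'
#' @param trace a [dense_trace()] or numeric vector.
#' @return Integer bin index (1-based).
#' @export
find_peak <- function(trace) {
  v <- if (inherits(trace, "dense_trace")) trace$values else trace
  if (length(v) == 0L) stop("empty trace")
  which.max(v)
}

#' Sample peak-aligned, evenly spaced gates
#'
#' Takes `n_gates` point samples of the dense trace starting at the peak
#' bin and stepping by `gate_spacing`, then max-normalizes the result so
#' the peak sample equals 1.  Peak alignment makes the sampling invariant
#' to per-pixel timing offsets.
#'
#' @param trace a [dense_trace()] or numeric vector.
#' @param peak peak bin index (1-based), e.g. from [find_peak()].
#' @param gate_spacing spacing between samples (ns); must be an integer
#'   multiple of the grid bin width.
#' @param n_gates number of samples.
#' @param dt grid bin width (ns); taken from the trace when it is a
#'   [dense_trace()].
#' @return Numeric vector of length `n_gates`, max-normalized (first
#'   element 1 for a noiseless trace).
#' @examples
#' g <- time_grid(0, 0.05, 400)
#' tr <- exp(-g$t / 1.5)
#' sample_gates(tr, 1L, gate_spacing = 1, dt = 0.05)
#' @export
sample_gates <- function(trace, peak, gate_spacing, n_gates = 6L, dt = NULL) {
  v <- if (inherits(trace, "dense_trace")) trace$values else trace
  if (inherits(trace, "dense_trace")) dt <- trace$grid$dt
  if (is.null(dt)) stop("'dt' is required when 'trace' is a plain vector")
  s <- gate_spacing / dt
  if (abs(s - round(s)) > 1e-8)
    stop("'gate_spacing' must be an integer multiple of the bin width")
  s <- as.integer(round(s))
  idx <- peak + (seq_len(n_gates) - 1L) * s
  if (idx[n_gates] > length(v))
    stop(sprintf(
      "insufficient tail: last gate needs bin %d but trace has %d bins (%d short)",
      idx[n_gates], length(v), idx[n_gates] - length(v)))
  out <- v[idx]
  mx <- max(out)
  if (mx > 0) out <- out / mx
  out
}

#' Gated image stack
#'
#' A `height x width x n_gates` array of peak-aligned, max-normalized gate
#' samples -- the input of every estimator -- carrying its gate spacing as
#' an attribute.
#'
#' @param values numeric `height x width x n_gates` array.
#' @param gate_spacing spacing between gates (ns).
#' @return The array with class `"gated_stack"` and attribute
#'   `gate_spacing`.
#' @export
gated_stack <- function(values, gate_spacing) {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  if (!is.numeric(gate_spacing) || gate_spacing <= 0)
    stop("'gate_spacing' must be positive")
  structure(values, gate_spacing = gate_spacing, class = "gated_stack")
}

#' @export
print.gated_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<gated_stack> %d x %d pixels, %d gates, spacing %g ns\n",
              d[1], d[2], d[3], attr(x, "gate_spacing")))
  invisible(x)
}

#' @rdname gated_stack
#' @param x object to query.
#' @export
gate_spacing <- function(x) attr(x, "gate_spacing")

# Simulate one image: per foreground pixel, decay -> convolve with the
# pixel's IRF -> max-normalize -> scale by A -> Poisson -> max-normalize
# -> peak-align -> sample n_gates gates -> max-normalize the gate vector.
#
# offsets: optional matrix of per-pixel timing offsets (ns) applied to the
# IRF center (rounded to whole bins); snr_target: optional scalar total
# count target that overrides the drawn amplitudes (A = target^2 / shape
# sum); noise: disable the Poisson step for noiseless data.
simulate_image <- function(cfg, height, width, noise = TRUE,
                           offsets = NULL, snr_target = NULL,
                           amp_bounds = NULL, return_dense = FALSE) {
  grid <- cfg$grid
  gt <- make_ground_truth(height, width, cfg)
  field <- irf_field(height, width, cfg)
  fg <- which(gt$mask)
  n_fg <- length(fg)
  gates <- array(0, c(height, width, cfg$n_gates))
  snr <- matrix(0, height, width)
  peak <- matrix(NA_integer_, height, width)
  bg_level <- cfg$background_noise_level

  dense <- if (return_dense)
    array(0, c(height, width, grid$n_bins)) else NULL
  if (n_fg > 0L) {
    off <- if (is.null(offsets)) numeric(n_fg) else {
      stopifnot(is.matrix(offsets), nrow(offsets) == height,
                ncol(offsets) == width)
      round(offsets[fg] / grid$dt) * grid$dt
    }
    if (any(cfg$irf_t0 + off + grid$t[1] < 0))
      warning("timing offsets push the IRF before the grid start")
    tau <- gt$tau[fg]
    decays <- exp(-outer(grid$t - grid$t[1], tau, "/"))
    u <- outer(grid$t, cfg$irf_t0 + off, "-") *
      (2 * (0.5 * log(2))^(1 / (2 * cfg$irf_order)))
    u <- sweep(u, 2L, field$fwhm[fg], "/")
    irfs <- exp(-2 * u^(2 * cfg$irf_order))
    shape <- conv_fft_mat(irfs, decays, grid$dt)
    shape <- sweep(shape, 2L, apply(shape, 2L, max), "/")  # normalize
    if (!is.null(snr_target)) {
      a <- snr_target^2 / colSums(shape)
      if (!is.null(amp_bounds)) {
        if (any(a < amp_bounds[1] | a > amp_bounds[2]))
          warning("SNR target outside amplitude bounds; closest achievable used")
        a <- pmin(pmax(a, amp_bounds[1]), amp_bounds[2])
      }
      gt$amplitude[fg] <- a
    }
    scaled <- sweep(shape, 2L, gt$amplitude[fg], "*")      # scale by A
    if (noise) {
      counts <- matrix(rpois(length(scaled), scaled + bg_level),
                       nrow(scaled))
    } else counts <- scaled
    if (return_dense) {
      for (k in seq_len(n_fg)) {
        idx <- arrayInd(fg[k], c(height, width))
        dense[idx[1], idx[2], ] <- counts[, k]
      }
    }
    snr[fg] <- sqrt(colSums(counts))
    mx <- apply(counts, 2L, max)
    mx[mx == 0] <- 1
    norm2 <- sweep(counts, 2L, mx, "/")                    # normalize again
    pk <- max.col(t(norm2), ties.method = "first")
    peak[fg] <- pk
    s <- as.integer(round(cfg$gate_spacing / grid$dt))
    last <- pk + (cfg$n_gates - 1L) * s
    if (any(last > grid$n_bins))
      stop("grid too short for the requested gates after the peak")
    gm <- matrix(0, n_fg, cfg$n_gates)
    for (k in seq_len(cfg$n_gates))
      gm[, k] <- norm2[cbind(pk + (k - 1L) * s, seq_len(n_fg))]
    gmx <- apply(gm, 1L, max)
    gmx[gmx == 0] <- 1
    gm <- gm / gmx                                          # gate-vector norm
    for (k in seq_len(cfg$n_gates)) {
      page <- matrix(0, height, width)
      page[fg] <- gm[, k]
      gates[, , k] <- page
    }
  }
  if (noise && bg_level > 0) {
    bg <- which(!gt$mask)
    if (length(bg) > 0L) {
      # background pixels carry pure Poisson background in their gates
      bgm <- matrix(rpois(length(bg) * cfg$n_gates, bg_level),
                    length(bg), cfg$n_gates)
      bmx <- apply(bgm, 1L, max)
      bmx[bmx == 0] <- 1
      bgm <- bgm / bmx
      for (k in seq_len(cfg$n_gates)) {
        page <- gates[, , k]
        page[bg] <- bgm[, k]
        gates[, , k] <- page
      }
    }
  }
  list(gates = gated_stack(gates, cfg$gate_spacing), truth = gt,
       snr = snr, peak = peak, irf = field, dense = dense)
}

#' Generate a paired synthetic dataset
#'
#' Runs the full generation flow for `n_images` images: per foreground
#' pixel, a mono-exponential decay is convolved with that pixel's
#' super-Gaussian IRF, max-normalized, scaled by its amplitude, Poisson
#' noise is added, the result is normalized again, and six evenly spaced
#' gates are sampled starting at the peak.  A master seed derives
#' independent per-image child seeds, so the dataset is bit-reproducible.
#'
#' @param cfg a [flim_sim_config()]; `cfg$seed` seeds the generation.
#' @param n_images number of images (>= 1).
#' @param height,width image dimensions in pixels.
#' @param noise add Poisson noise (`TRUE`, the study condition) or return
#'   noiseless gates.
#' @return An object of class `"flim_dataset"`: list with arrays `gates`
#'   (`height x width x n_gates x n_images`), `tau`, `amplitude`, `snr`
#'   (`height x width x n_images`), logical `mask`, and the `cfg` used.
#' @examples
#' ds <- generate_dataset(flim_sim_config(seed = 1), 2, 16, 16)
#' dim(ds$gates)
#' @export
generate_dataset <- function(cfg, n_images, height = 128L, width = 128L,
                             noise = TRUE) {
  n_images <- as.integer(n_images)
  if (is.na(n_images) || n_images < 1L) stop("'n_images' must be >= 1")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  child <- sample.int(.Machine$integer.max - 1L, n_images)
  gates <- array(0, c(height, width, cfg$n_gates, n_images))
  tau <- amp <- snr <- array(0, c(height, width, n_images))
  mask <- array(FALSE, c(height, width, n_images))
  for (i in seq_len(n_images)) {
    set.seed(child[i])
    im <- simulate_image(cfg, height, width, noise = noise)
    gates[, , , i] <- unclass(im$gates)
    tau[, , i] <- im$truth$tau
    amp[, , i] <- im$truth$amplitude
    snr[, , i] <- im$snr
    mask[, , i] <- im$truth$mask
  }
  structure(list(gates = gates, tau = tau, amplitude = amp, snr = snr,
                 mask = mask, cfg = cfg, child_seeds = child),
            class = "flim_dataset")
}

#' @export
print.flim_dataset <- function(x, ...) {
  d <- dim(x$gates)
  cat(sprintf(
    "<flim_dataset> %d images of %d x %d pixels, %d gates (spacing %g ns)\n",
    d[4], d[1], d[2], d[3], x$cfg$gate_spacing))
  cat(sprintf("  foreground fraction %.2f; median per-pixel SNR %.1f\n",
              mean(x$mask), stats::median(x$snr[x$mask])))
  invisible(x)
}
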