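#' Classical lifetime fit result
#'
#' @param tau lifetime (ns).
#' @param amplitude pre-exponential (counts).
#' @param offset constant baseline (counts).
#' @param residual_norm Euclidean norm of the final residual.
#' @param converged logical convergence status.
#' @param n_iterations iterations used.
#' @param flag optional character note (e.g. why a fit is invalid).
#' @return An object of class `"flim_fit"`.
#' @export
flim_fit <- function(tau, amplitude = NA_real_, offset = 0,
                     residual_norm = NA_real_, converged = TRUE,
                     n_iterations = 0L, flag = NULL) {
  structure(list(tau = tau, amplitude = amplitude, offset = offset,
                 residual_norm = residual_norm, converged = converged,
                 n_iterations = as.integer(n_iterations), flag = flag),
            class = "flim_fit")
}

#' @export
print.flim_fit <- function(x, ...) {
  cat(sprintf(
    "<flim_fit> tau = %.4g ns, A = %.4g, offset = %.4g (%s, %d iter%s)\n",
    x$tau, x$amplitude, x$offset,
    if (isTRUE(x$converged)) "converged" else "NOT converged",
    x$n_iterations,
    if (is.null(x$flag)) "" else paste0("; ", x$flag)))
  invisible(x)
}

#' Full-decay re-convolution curve fitting
#'
#' Fits `conv(IRF, A * exp(-t / tau)) + offset` to a dense trace by damped
#' (Levenberg--Marquardt) nonlinear least squares.  This is the reference
#' estimator when the IRF is known; it is exact on noiseless simulator
#' output.
#'
#' @param trace a [dense_trace()] (the measured decay).
#' @param irf the pixel's [irf_params()]; the trace and the IRF share the
#'   trace's grid.
#' @param grid optional [time_grid()] override (defaults to the trace's).
#' @param init optional named list with starting values `tau`, `amplitude`,
#'   `offset`; sensible defaults are derived from the trace.
#' @param fit_offset include a constant baseline term (default `TRUE`).
#' @param tau_bounds lifetime search interval (ns).
#' @param max_iter Levenberg--Marquardt iteration cap.
#' @return A [flim_fit()]; `converged = FALSE` (never silent) when the
#'   iteration cap is hit.
#' @examples
#' g <- time_grid()
#' tr <- simulate_decay(1.2, 60, irf_params(10, 4.2, 4), g)
#' reconvolution_fit(tr, irf_params(10, 4.2, 4))$tau
#' @export
reconvolution_fit <- function(trace, irf, grid = NULL, init = NULL,
                              fit_offset = TRUE, tau_bounds = c(0.05, 10),
                              max_iter = 100L) {
  stopifnot(inherits(trace, "dense_trace"))
  grid <- if (is.null(grid)) trace$grid else grid
  irf <- irf_params(irf$t0, irf$fwhm, irf$order)
  y <- trace$values
  kern <- super_gaussian_irf(grid$t, irf$t0, irf$fwhm, irf$order)
  base_decay <- function(tau) exp(-(grid$t - grid$t[1]) / tau)
  shape1 <- conv_fft(kern, base_decay(1), grid$dt)
  p0 <- list(tau = 1, amplitude = max(y) / max(shape1), offset = min(y))
  if (!is.null(init)) p0 <- modifyList(p0, init[!vapply(init, is.null, TRUE)])
  par <- c(tau = p0$tau, amplitude = p0$amplitude)
  lower <- c(tau_bounds[1], 1e-12)
  upper <- c(tau_bounds[2], Inf)
  if (fit_offset) {
    par <- c(par, offset = p0$offset)
    lower <- c(lower, -Inf); upper <- c(upper, Inf)
  }
  resid_fn <- function(p) {
    model <- p[["amplitude"]] * conv_fft(kern, base_decay(p[["tau"]]), grid$dt)
    if (fit_offset) model <- model + p[["offset"]]
    model - y
  }
  fit <- minpack.lm::nls.lm(par = par, lower = lower, upper = upper,
                            fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = max_iter))
  est <- fit$par
  flim_fit(tau = est[["tau"]], amplitude = est[["amplitude"]],
           offset = if (fit_offset) est[["offset"]] else 0,
           residual_norm = sqrt(fit$deviance),
           converged = fit$info %in% 1:4,
           n_iterations = fit$niter)
}

#' Six-point tail fitting
#'
#' Fits `B * exp(-k * gate_spacing / tau)` to the peak-aligned gate vector
#' (`k = 0, ..., n_gates - 1`) without any IRF term.  The fit runs in
#' nonlinear space (Levenberg--Marquardt, initialized from the log-linear
#' regression); a log-linear fast path is available.  With a broad gate
#' relative to the lifetime, ignoring the IRF biases the estimate upward.
#'
#' @param gates normalized gate vector; first element is the peak sample.
#' @param gate_spacing spacing between samples (ns).
#' @param log_linear use the log-linear regression estimate directly.
#' @return A [flim_fit()]; non-positive samples are dropped and the fit is
#'   flagged (`converged = FALSE`) when fewer than 3 points remain or the
#'   decay is non-identifiable (flat or rising).
#' @examples
#' r <- exp(-1 / 1.5)
#' tail_fit(r^(0:5), gate_spacing = 1)$tau  # 1.5
#' @export
tail_fit <- function(gates, gate_spacing, log_linear = FALSE) {
  stopifnot(is.numeric(gates), length(gates) >= 2L, gate_spacing > 0)
  k <- seq_along(gates) - 1
  pos <- gates > 1e-12
  if (sum(pos) < 3L)
    return(flim_fit(NA_real_, converged = FALSE,
                    flag = "fewer than 3 positive samples"))
  tk <- k[pos] * gate_spacing
  lg <- log(gates[pos])
  co <- stats::coef(stats::lm(lg ~ tk))
  slope <- co[[2]]
  if (!is.finite(slope) || slope >= -1e-9)
    return(flim_fit(NA_real_, converged = FALSE,
                    flag = "non-decaying samples: lifetime unbounded"))
  tau0 <- -1 / slope
  b0 <- exp(co[[1]])
  if (log_linear)
    return(flim_fit(tau0, amplitude = b0,
                    residual_norm = sqrt(sum((b0 * exp(-tk / tau0) -
                                                gates[pos])^2)),
                    converged = TRUE, n_iterations = 0L))
  fit <- minpack.lm::nls.lm(
    par = c(tau = tau0, b = b0),
    lower = c(1e-3, 1e-12), upper = c(1e3, Inf),
    fn = function(p) p[["b"]] * exp(-tk / p[["tau"]]) - gates[pos],
    control = minpack.lm::nls.lm.control(maxiter = 100L))
  flim_fit(fit$par[["tau"]], amplitude = fit$par[["b"]],
           residual_norm = sqrt(fit$deviance),
           converged = fit$info %in% 1:4, n_iterations = fit$niter)
}

#' Rapid lifetime determination (RLD)
#'
#' Closed-form two-gate estimate `tau = gate_spacing / log(I1 / I2)` from
#' the first two post-peak samples.
#'
#' @param gates gate vector (first two entries used).
#' @param gate_spacing spacing between the two gates (ns).
#' @return A [flim_fit()]; flagged invalid when `I1 <= I2` or either gate
#'   is non-positive.
#' @examples
#' rld(c(100, 100 / exp(1)), 1)$tau  # 1
#' @export
rld <- function(gates, gate_spacing) {
  stopifnot(is.numeric(gates), length(gates) >= 2L, gate_spacing > 0)
  i1 <- gates[1]; i2 <- gates[2]
  if (!(i1 > 0 && i2 > 0))
    return(flim_fit(NA_real_, converged = FALSE,
                    flag = "non-positive gate intensities"))
  if (i1 <= i2)
    return(flim_fit(NA_real_, converged = FALSE,
                    flag = "I1 <= I2: lifetime undefined"))
  flim_fit(gate_spacing / log(i1 / i2), amplitude = i1)
}

#' Pulsed-excitation phasor analysis
#'
#' Maps a decay to its Fourier coordinates at angular frequency `omega`:
#' `g = sum(D cos(wt)) / sum(D)`, `s = sum(D sin(wt)) / sum(D)`.  For a
#' mono-exponential decay the point lies on the universal semicircle
#' `(g - 1/2)^2 + s^2 = 1/4` and the lifetime is `tau = s / (omega * g)`.
#' Because the phase is referenced to the measurement window, per-pixel
#' timing offsets translate directly into lifetime errors.
#'
#' @param x a [dense_trace()], or a numeric vector of intensities with
#'   sample times `t`.
#' @param omega angular frequency (rad/ns); defaults to one cycle over the
#'   measurement window, `2 * pi / T`.
#' @param t sample times (ns) when `x` is a plain vector.
#' @return An object of class `"phasor_point"`: list with `g`, `s`,
#'   `omega`, `tau` (`NA` and flagged when `g <= 0`) and `valid`.
#' @examples
#' tt <- seq(0, 60, by = 0.01)
#' ph <- phasor(exp(-tt), omega = 1, t = tt)
#' c(ph$g, ph$s, ph$tau)
#' @export
phasor <- function(x, omega = NULL, t = NULL) {
  if (inherits(x, "dense_trace")) {
    t <- x$grid$t - x$grid$t[1]
    v <- x$values
  } else {
    v <- x
    if (is.null(t)) stop("'t' is required when 'x' is a plain vector")
    t <- t - t[1]
  }
  tot <- sum(v)
  if (tot <= 0) stop("phasor requires non-zero total intensity")
  if (is.null(omega)) omega <- 2 * pi / (max(t) - min(t) + (t[2] - t[1]))
  g <- sum(v * cos(omega * t)) / tot
  s <- sum(v * sin(omega * t)) / tot
  valid <- g > 0
  structure(list(g = g, s = s, omega = omega,
                 tau = if (valid) s / (omega * g) else NA_real_,
                 valid = valid,
                 flag = if (valid) NULL else "g <= 0: lifetime undefined"),
            class = "phasor_point")
}

#' @export
print.phasor_point <- function(x, ...) {
  cat(sprintf("<phasor_point> g = %.4f, s = %.4f (omega = %.4g rad/ns), tau = %.4g ns\n",
              x$g, x$s, x$omega, x$tau))
  invisible(x)
}

#' Per-pixel lifetime map
#'
#' @param tau matrix of lifetime estimates (ns).
#' @param valid logical matrix of per-pixel validity flags.
#' @param method estimator tag.
#' @return An object of class `"lifetime_map"`.
#' @export
lifetime_map <- function(tau, valid = is.finite(tau), method = "unknown") {
  stopifnot(is.matrix(tau), is.matrix(valid), all(dim(tau) == dim(valid)))
  structure(list(tau = tau, valid = valid, method = method),
            class = "lifetime_map")
}

#' @export
print.lifetime_map <- function(x, ...) {
  n <- sum(x$valid)
  cat(sprintf("<lifetime_map> %d x %d (%s), %d valid pixels",
              nrow(x$tau), ncol(x$tau), x$method, n))
  if (n > 0)
    cat(sprintf(", mean tau = %.3f ns", mean(x$tau[x$valid])))
  cat("\n")
  invisible(x)
}

#' Apply an estimator to every pixel of an image
#'
#' Runs a gate-domain estimator (`tail`, `rld`, `phasor`) on a
#' [gated_stack()], or the re-convolution fit (`reconv`) on a dense
#' `height x width x n_bins` stack with a known per-pixel IRF field.
#' Background pixels (all-zero gate vectors) and per-pixel fit failures
#' are marked invalid, never aborting the image.
#'
#' @param stack a [gated_stack()] (for `tail`, `rld`, `phasor`) or dense
#'   array (for `reconv`).
#' @param method one of `"tail"`, `"rld"`, `"phasor"`, `"reconv"`.
#' @param irf an [irf_field()], required for `"reconv"`.
#' @param grid [time_grid()] of the dense stack, required for `"reconv"`.
#' @param omega phasor angular frequency (rad/ns); default one cycle over
#'   the gate window.
#' @param ... passed to the per-pixel estimator.
#' @return A [lifetime_map()].
#' @export
fit_image <- function(stack, method = c("tail", "rld", "phasor", "reconv"),
                      irf = NULL, grid = NULL, omega = NULL, ...) {
  method <- match.arg(method)
  if (method == "reconv") {
    stopifnot(is.array(stack), length(dim(stack)) == 3L,
              inherits(irf, "irf_field"), is_time_grid(grid))
    h <- dim(stack)[1]; w <- dim(stack)[2]
    tau <- matrix(NA_real_, h, w); valid <- matrix(FALSE, h, w)
    for (i in seq_len(h)) for (j in seq_len(w)) {
      v <- stack[i, j, ]
      if (all(v == 0)) next
      f <- tryCatch(
        reconvolution_fit(dense_trace(v, grid,
                                      if (all(v == round(v))) "poisson"
                                      else "none"),
                          irf_params(irf$t0, irf$fwhm[i, j], irf$order),
                          ...),
        error = function(e) flim_fit(NA_real_, converged = FALSE,
                                     flag = conditionMessage(e)))
      if (isTRUE(f$converged) && is.finite(f$tau) && f$tau > 0) {
        tau[i, j] <- f$tau; valid[i, j] <- TRUE
      }
    }
  } else {
    stopifnot(inherits(stack, "gated_stack"))
    h <- dim(stack)[1]; w <- dim(stack)[2]
    sp <- gate_spacing(stack)
    tg <- (seq_len(dim(stack)[3]) - 1) * sp
    tau <- matrix(NA_real_, h, w); valid <- matrix(FALSE, h, w)
    for (i in seq_len(h)) for (j in seq_len(w)) {
      g <- stack[i, j, ]
      if (all(g == 0)) next
      est <- switch(method,
        tail = tail_fit(g, sp, ...),
        rld = rld(g, sp, ...),
        phasor = {
          p <- phasor(g, omega = omega, t = tg)
          flim_fit(p$tau, converged = p$valid, flag = p$flag)
        })
      if (isTRUE(est$converged) && is.finite(est$tau) && est$tau > 0) {
        tau[i, j] <- est$tau; valid[i, j] <- TRUE
      }
    }
  }
  if (!any(valid)) warning("no valid pixels in the fitted image")
  lifetime_map(tau, valid, method)
}
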