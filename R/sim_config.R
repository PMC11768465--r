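#' Simulation configuration
#'
#' Bundles every knob of the synthetic time-gated decay generator.  The
#' defaults reproduce the study conditions used throughout the package:
#' per-pixel lifetimes uniform on 0.6--2 ns, pre-exponential amplitudes
#' uniform on 20--100 counts, per-pixel super-Gaussian IRFs of order 4 with
#' FWHM uniform on 4--4.5 ns, Poisson shot noise, and six gate samples
#' 1 ns apart starting at the decay peak.
#'
#' @param tau_range lifetime range (ns) for foreground pixels, `c(lo, hi)`.
#' @param amp_range pre-exponential amplitude range (counts).
#' @param fwhm_range IRF full-width-at-half-maximum range (ns).
#' @param irf_order super-Gaussian order `N`.
#' @param irf_t0 IRF pulse center on the dense grid (ns).
#' @param gate_spacing spacing between consecutive gate samples (ns); must
#'   be an integer multiple of `grid$dt` and identical between training and
#'   inference.
#' @param n_gates number of gate samples per pixel.
#' @param grid dense [time_grid()] on which decays are evaluated before
#'   gate sampling.
#' @param mask_source `"procedural_digits"` for the bundled generator of
#'   digit-like connected strokes, or `"user_supplied"` together with
#'   `mask`.
#' @param mask optional logical matrix used when
#'   `mask_source = "user_supplied"`.
#' @param background_noise_level constant Poisson background mean added to
#'   every bin (counts); the default 0 simulates shot noise only, so
#'   background pixels are exactly zero.
#' @param seed master RNG seed; per-image child seeds are derived from it
#'   so each image is reproducible independently of generation order.
#' @return An object of class `"flim_sim_config"`.
#' @examples
#' cfg <- flim_sim_config(seed = 7)
#' cfg
#' @export
flim_sim_config <- function(tau_range = c(0.6, 2),
                            amp_range = c(20, 100),
                            fwhm_range = c(4, 4.5),
                            irf_order = 4L,
                            irf_t0 = 10,
                            gate_spacing = 1,
                            n_gates = 6L,
                            grid = time_grid(0, 0.05, 1000L),
                            mask_source = c("procedural_digits",
                                            "user_supplied"),
                            mask = NULL,
                            background_noise_level = 0,
                            seed = NULL) {
  mask_source <- match.arg(mask_source)
  chk_range <- function(r, name, positive = TRUE) {
    if (!is.numeric(r) || length(r) != 2L || anyNA(r) || r[1] > r[2])
      stop(sprintf("'%s' must be c(lo, hi) with lo <= hi", name))
    if (positive && r[1] <= 0)
      stop(sprintf("'%s' must be positive", name))
  }
  chk_range(tau_range, "tau_range")
  chk_range(amp_range, "amp_range")
  chk_range(fwhm_range, "fwhm_range")
  stopifnot(is_time_grid(grid))
  if (gate_spacing <= 0) stop("'gate_spacing' must be positive")
  s <- gate_spacing / grid$dt
  if (abs(s - round(s)) > 1e-8)
    stop("'gate_spacing' must be an integer multiple of grid$dt")
  n_gates <- as.integer(n_gates)
  if (is.na(n_gates) || n_gates < 2L) stop("'n_gates' must be >= 2")
  if (background_noise_level < 0)
    stop("'background_noise_level' must be >= 0")
  if (mask_source == "user_supplied") {
    if (is.null(mask) || !is.matrix(mask) || !is.logical(mask))
      stop("mask_source = 'user_supplied' requires a logical matrix 'mask'")
  }
  structure(
    list(tau_range = tau_range, amp_range = amp_range,
         fwhm_range = fwhm_range, irf_order = as.integer(irf_order),
         irf_t0 = irf_t0, gate_spacing = gate_spacing, n_gates = n_gates,
         grid = grid, mask_source = mask_source, mask = mask,
         background_noise_level = background_noise_level, seed = seed),
    class = "flim_sim_config")
}

#' @export
print.flim_sim_config <- function(x, ...) {
  cat("<flim_sim_config>\n")
  cat(sprintf("  tau ~ U[%g, %g] ns, A ~ U[%g, %g] counts\n",
              x$tau_range[1], x$tau_range[2], x$amp_range[1], x$amp_range[2]))
  cat(sprintf("  IRF: super-Gaussian N = %d, FWHM ~ U[%g, %g] ns, t0 = %g ns\n",
              x$irf_order, x$fwhm_range[1], x$fwhm_range[2], x$irf_t0))
  cat(sprintf("  %d gates, spacing %g ns; grid dt = %g ns, %d bins\n",
              x$n_gates, x$gate_spacing, x$grid$dt, x$grid$n_bins))
  cat(sprintf("  masks: %s; background level %g; seed %s\n",
              x$mask_source, x$background_noise_level,
              if (is.null(x$seed)) "unset" else x$seed))
  invisible(x)
}
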