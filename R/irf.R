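#' Super-Gaussian instrument response function
#'
#' The IRF of a time-gated sensor is dominated by its gate window: a flat
#' top with steep edges, well modelled by a super-Gaussian of order `N`,
#'
#' \deqn{IRF(t) = \exp\!\left[-2\left(\frac{2 (t - t_0)\,(0.5\ln 2)^{1/(2N)}}
#'   {FWHM}\right)^{2N}\right]}
#'
#' which attains 1 at `t0` and exactly 0.5 at `t0 +/- fwhm/2` for every
#' order, so that `fwhm` is the literal full width at half maximum.
#'
#' @param t time (ns); vectorized.
#' @param t0 center of the pulse (ns).
#' @param fwhm full width at half maximum (ns), positive.
#' @param order super-Gaussian order `N` (integer >= 1); `order = 1` is an
#'   ordinary Gaussian, larger orders approach a rectangular gate.
#' @return Unitless intensities in `[0, 1]`, same length as `t`.
#' @examples
#' super_gaussian_irf(10, t0 = 10, fwhm = 4, order = 4)        # 1
#' super_gaussian_irf(12, t0 = 10, fwhm = 4, order = 4)        # 0.5
#' @export
super_gaussian_irf <- function(t, t0, fwhm, order = 4L) {
  if (!is.numeric(t) || anyNA(t) || any(!is.finite(t)))
    stop("'t' must be finite numeric")
  p <- irf_params(t0 = t0, fwhm = fwhm, order = order)
  u <- 2 * (t - p$t0) * (0.5 * log(2))^(1 / (2 * p$order)) / p$fwhm
  exp(-2 * u^(2 * p$order))
}

#' Per-pixel IRF parameters
#'
#' @param t0 pulse center (ns).
#' @param fwhm full width at half maximum (ns), positive.
#' @param order super-Gaussian order, integer >= 1.
#' @return An object of class `"irf_params"`.
#' @export
irf_params <- function(t0, fwhm, order = 4L) {
  if (inherits(t0, "irf_params")) return(t0)
  stopifnot(is.numeric(t0), length(t0) == 1L, is.finite(t0))
  if (!is.numeric(fwhm) || length(fwhm) != 1L || !is.finite(fwhm) || fwhm <= 0)
    stop("'fwhm' must be a single positive number")
  order <- as.integer(order)
  if (is.na(order) || order < 1L) stop("'order' must be an integer >= 1")
  structure(list(t0 = t0, fwhm = fwhm, order = order), class = "irf_params")
}

#' @export
print.irf_params <- function(x, ...) {
  cat(sprintf("<irf_params> t0 = %g ns, FWHM = %g ns, order N = %d\n",
              x$t0, x$fwhm, x$order))
  invisible(x)
}

#' Draw a per-pixel IRF field
#'
#' Each pixel receives its own IRF with FWHM drawn independently and
#' uniformly from `cfg$fwhm_range` (the pulse center `t0` and order are
#' shared, taken from the configuration).  At the native 128 x 128 sensor
#' resolution this yields 16,384 distinct IRFs per image.
#'
#' @param height,width image dimensions in pixels (>= 1).
#' @param cfg a [flim_sim_config()].
#' @return An object of class `"irf_field"`: list with `height`, `width`,
#'   `t0`, `order` and the `height x width` matrix `fwhm`.
#' @examples
#' f <- irf_field(4, 4, flim_sim_config(seed = 1))
#' range(f$fwhm)
#' @export
irf_field <- function(height, width, cfg = flim_sim_config()) {
  height <- as.integer(height); width <- as.integer(width)
  if (is.na(height) || height < 1L || is.na(width) || width < 1L)
    stop("'height' and 'width' must be integers >= 1")
  r <- cfg$fwhm_range
  if (length(r) != 2L || anyNA(r) || r[1] > r[2] || r[1] <= 0)
    stop("invalid 'fwhm_range' in configuration")
  fwhm <- matrix(runif(height * width, r[1], r[2]), height, width)
  structure(list(height = height, width = width, t0 = cfg$irf_t0,
                 order = cfg$irf_order, fwhm = fwhm),
            class = "irf_field")
}

#' @export
print.irf_field <- function(x, ...) {
  cat(sprintf("<irf_field> %d x %d (%d IRFs), FWHM in [%.3f, %.3f] ns, N = %d\n",
              x$height, x$width, x$height * x$width,
              min(x$fwhm), max(x$fwhm), x$order))
  invisible(x)
}
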