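#' Uniform dense time axis
#'
#' Decays and IRFs are evaluated on a dense, uniformly spaced grid before
#' the six gate samples are taken.  Bin centers are
#' `t_k = t_start + k * dt`, `k = 0, ..., n_bins - 1`.
#'
#' @param t_start start of the axis (ns).
#' @param dt bin width (ns), must be positive.
#' @param n_bins number of bins, at least 2.
#' @return An object of class `"time_grid"` with fields `t_start`, `dt`,
#'   `n_bins` and the precomputed bin centers `t`.
#' @examples
#' g <- time_grid()
#' range(g$t)
#' @export
time_grid <- function(t_start = 0, dt = 0.05, n_bins = 1000L) {
  stopifnot(is.numeric(t_start), length(t_start) == 1L, is.finite(t_start))
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("'dt' must be a single positive number")
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 2L)
    stop("'n_bins' must be an integer >= 2")
  structure(
    list(t_start = t_start, dt = dt, n_bins = n_bins,
         t = t_start + (seq_len(n_bins) - 1) * dt),
    class = "time_grid")
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf("<time_grid> %d bins, dt = %g ns, [%g, %g] ns\n",
              x$n_bins, x$dt, x$t[1], x$t[x$n_bins]))
  invisible(x)
}

is_time_grid <- function(x) inherits(x, "time_grid")
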