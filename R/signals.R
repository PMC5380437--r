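#' @useDynLib tutorsim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rpois quantile sd
#' @importFrom utils read.csv write.csv head tail
NULL

#' Uniform time grid for a motor program
#'
#' All signals in the package live on a shared uniformly sampled time grid
#' covering one rendition of the motor program. The default duration is 1 s,
#' the scale of a songbird motif, and the default step is 1 ms, appropriate
#' for rate-based simulations (spiking runs use 0.1 ms; see
#' [spiking_params()]).
#'
#' @param t_start Start time in seconds.
#' @param t_end End time in seconds (duration of the motor program).
#' @param dt Sampling step in seconds.
#' @return An object of class `"time_grid"` with elements `t_start`, `t_end`,
#'   `dt`, `n` (number of samples) and `times` (the sample times).
#' @examples
#' g <- time_grid(0, 1, 0.001)
#' g$n
#' @export
time_grid <- function(t_start = 0, t_end = 1, dt = 1e-3) {
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0) {
    stop("`dt` must be a positive number", call. = FALSE)
  }
  if (t_end <= t_start) stop("`t_end` must exceed `t_start`", call. = FALSE)
  n <- round((t_end - t_start) / dt) + 1L
  if (n < 2) stop("grid must contain at least 2 samples", call. = FALSE)
  structure(
    list(t_start = t_start, t_end = t_end, dt = dt, n = as.integer(n),
         times = t_start + dt * (seq_len(n) - 1)),
    class = "time_grid"
  )
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf("<time_grid> [%g, %g] s, dt = %g s, %d samples\n",
              x$t_start, x$t_end, x$dt, x$n))
  invisible(x)
}

#' Multi-channel sampled signal
#'
#' A signal holds one or more channels (neurons, output channels, reward)
#' sampled on a common [time_grid()]. Values are stored as a matrix with one
#' row per channel and one column per time sample.
#'
#' @param values Numeric matrix (channels x samples) or a vector for a single
#'   channel.
#' @param grid A [time_grid()].
#' @param units Free-form unit label ("Hz", "mV", "" for dimensionless).
#' @return An object of class `"signal"`.
#' @examples
#' g <- time_grid(0, 0.1, 0.001)
#' s <- signal(sin(2 * pi * 5 * g$times), g, units = "Hz")
#' @export
signal <- function(values, grid, units = "") {
  if (!inherits(grid, "time_grid")) stop("`grid` must be a time_grid",
                                         call. = FALSE)
  if (is.vector(values)) values <- matrix(values, nrow = 1)
  if (!is.matrix(values)) values <- as.matrix(values)
  if (ncol(values) != grid$n) {
    stop(sprintf("signal has %d samples but grid has %d",
                 ncol(values), grid$n), call. = FALSE)
  }
  if (!all(is.finite(values))) stop("signal values must all be finite",
                                    call. = FALSE)
  structure(list(values = values, grid = grid, units = units),
            class = "signal")
}

#' @export
print.signal <- function(x, ...) {
  cat(sprintf("<signal> %d channel(s) x %d samples on [%g, %g] s%s\n",
              nrow(x$values), ncol(x$values), x$grid$t_start, x$grid$t_end,
              if (nzchar(x$units)) paste0(" [", x$units, "]") else ""))
  invisible(x)
}

#' @export
as.matrix.signal <- function(x, ...) x$values

#' Number of channels in a signal
#' @param x A [signal()].
#' @return Integer channel count.
#' @export
n_channels <- function(x) nrow(x$values)

#' Causal exponential filter
#'
#' Filters each channel with a causal exponential kernel starting from zero
#' state at the first sample:
#' \deqn{y(t) = \frac{1}{\tau}\int_0^t x(t')\,e^{-(t-t')/\tau}\,dt'}
#' (normalized kernel), or the unnormalized variant without the \eqn{1/\tau}
#' prefactor as used for the motor-output smoothing. The discrete recursion is
#' algebraically identical to trapezoid quadrature of the convolution
#' integral.
#'
#' @param x A [signal()], or a numeric matrix/vector (then `dt` is required).
#' @param tau Filter timescale in seconds; must be positive.
#' @param normalized If `TRUE` (default) the kernel integrates to 1.
#' @param init Initial filter state (scalar or one value per channel);
#'   defaults to zero, matching integrals that start at t = 0.
#' @param dt Sampling step, only used when `x` is not a signal.
#' @return Filtered object of the same shape as the input.
#' @examples
#' g <- time_grid(0, 0.5, 1e-3)
#' x <- signal(rep(1, g$n), g)
#' y <- exp_filter(x, 0.05) # approaches 1 - exp(-t / 0.05)
#' @export
exp_filter <- function(x, tau, normalized = TRUE, init = 0, dt = NULL) {
  if (!is.numeric(tau) || length(tau) != 1 || !is.finite(tau) || tau <= 0) {
    stop("`tau` must be a positive number", call. = FALSE)
  }
  if (inherits(x, "signal")) {
    y <- .expfilt_mat(x$values, x$grid$dt, tau, normalized, as.numeric(init))
    return(signal(y, x$grid, units = x$units))
  }
  if (is.null(dt)) stop("`dt` is required for matrix input", call. = FALSE)
  vec <- is.vector(x)
  if (vec) x <- matrix(x, nrow = 1)
  y <- .expfilt_mat(x, dt, tau, normalized, as.numeric(init))
  if (vec) drop(y) else y
}

#' Trapezoid quadrature of each channel over the grid
#'
#' @param x A [signal()].
#' @return Numeric vector, one integral per channel.
#' @export
integrate_signal <- function(x) {
  w <- trapz_weights(x$grid$n, x$grid$dt)
  as.numeric(x$values %*% w)
}

trapz_weights <- function(n, dt) {
  w <- rep(dt, n)
  w[c(1, n)] <- dt / 2
  w
}
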