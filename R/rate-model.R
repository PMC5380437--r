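#' Conductor-student-output network state
#'
#' Holds the plastic conductor-to-student weights `W`, the fixed
#' student-to-output map `M`, the tutor-to-student gain `w` and the constant
#' inhibitory bias `x_inh` of the linear rate model. Student activity is
#' \deqn{s_j(t) = \sum_i W_{ij} c_i(t) + w\,g_j(t) - x_{inh},}
#' and the motor output combines student rates through `M` followed by an
#' exponential smoothing that mimics muscle response times.
#'
#' @param W Numeric matrix, `n_conductor x n_student`.
#' @param M Numeric matrix, `n_channels x n_student` (see [output_map()]).
#' @param w Scalar tutor-to-student gain.
#' @param x_inh Scalar constant inhibitory bias (same units as student rates).
#' @param positivity If `TRUE`, `W` entries are required (and kept) >= 0.
#' @return An object of class `"network_state"`.
#' @export
network_state <- function(W, M, w = 1, x_inh = 0, positivity = FALSE) {
  W <- as.matrix(W); M <- as.matrix(M)
  if (ncol(W) != ncol(M)) {
    stop("W and M disagree on the number of student neurons", call. = FALSE)
  }
  if (positivity && any(W < 0)) {
    stop("positivity constraint enabled but W has negative entries",
         call. = FALSE)
  }
  structure(list(W = W, M = M, w = w, x_inh = x_inh, positivity = positivity),
            class = "network_state")
}

#' @export
print.network_state <- function(x, ...) {
  cat(sprintf(paste0("<network_state> %d conductor -> %d student -> ",
                     "%d channel(s); w = %g, x_inh = %g\n"),
              nrow(x$W), ncol(x$W), nrow(x$M), x$w, x$x_inh))
  invisible(x)
}

#' Student-to-output assignment matrix
#'
#' Each student neuron contributes to exactly one output channel, mirroring
#' the dedicated projection of RA neurons to muscle-related outputs. Students
#' are assigned to channels in contiguous blocks and each channel averages its
#' block with equal weights `1 / (students per channel)`.
#'
#' @param n_student Number of student neurons (a multiple of `n_channels`).
#' @param n_channels Number of output channels (default 2).
#' @return `n_channels x n_student` matrix.
#' @export
output_map <- function(n_student, n_channels = 2) {
  if (n_student %% n_channels != 0) {
    stop("`n_student` must be a multiple of `n_channels`", call. = FALSE)
  }
  per <- n_student / n_channels
  M <- matrix(0, n_channels, n_student)
  for (a in seq_len(n_channels)) {
    M[a, ((a - 1) * per + 1):(a * per)] <- 1 / per
  }
  M
}

#' Conductor firing-rate program
#'
#' Each conductor neuron is active during exactly one contiguous burst window
#' of length `burst_len` (default 10 ms), at a constant rate, with burst
#' onsets spread evenly to tile the motor program, as in the sparse,
#' precisely timed bursting of HVC projection neurons. By default the burst
#' amplitude is scaled so that the summed conductor drive
#' \eqn{\sum_i c_i(t)} is approximately 1 throughout the program, giving
#' uniform drive regardless of population size.
#'
#' @param grid A [time_grid()].
#' @param n_conductor Number of conductor neurons.
#' @param burst_len Burst duration in seconds (default 0.01).
#' @param burst_rate Rate during the burst; `NULL` (default) auto-scales so
#'   the population drive sums to about 1.
#' @return A [signal()] with one row per conductor neuron.
#' @export
generate_conductor_rates <- function(grid, n_conductor, burst_len = 0.01,
                                     burst_rate = NULL) {
  T <- grid$t_end - grid$t_start
  if (burst_len > T) {
    stop("`burst_len` exceeds the program duration", call. = FALSE)
  }
  if (is.null(burst_rate)) {
    # mean number of simultaneously active neurons is n * burst_len / T
    burst_rate <- T / (n_conductor * burst_len)
  }
  # index-based windows: every burst spans exactly the same number of
  # samples and even tiling leaves no single-sample gaps
  blen_steps <- max(1L, as.integer(round(burst_len / grid$dt)))
  vals <- matrix(0, n_conductor, grid$n)
  spacing <- (T - burst_len) / max(1, n_conductor - 1)
  for (i in seq_len(n_conductor)) {
    start <- 1L + as.integer(round((i - 1) * spacing / grid$dt))
    stop_i <- min(start + blen_steps - 1L, grid$n)
    vals[i, start:stop_i] <- burst_rate
  }
  signal(vals, grid, units = "Hz")
}

#' Student firing rates of the linear rate model
#'
#' @param state A [network_state()].
#' @param c_sig Conductor rates, one row per conductor neuron.
#' @param g Tutor signal, one row per student neuron, or `NULL` for no tutor
#'   drive.
#' @return A [signal()] of student rates (one row per student neuron).
#' @export
student_rates <- function(state, c_sig, g = NULL) {
  if (nrow(c_sig$values) != nrow(state$W)) {
    stop("conductor signal rows do not match nrow(W)", call. = FALSE)
  }
  s <- crossprod(state$W, c_sig$values) - state$x_inh
  if (!is.null(g)) {
    if (nrow(g$values) != ncol(state$W)) {
      stop("tutor signal rows do not match ncol(W)", call. = FALSE)
    }
    s <- s + state$w * g$values
  }
  signal(s, c_sig$grid, units = "Hz")
}

#' Smoothed motor output
#'
#' Combines student rates through the output map and smooths with an
#' unnormalized causal exponential kernel,
#' \deqn{\tilde y_a(t) = \sum_j M_{aj} \int_0^t s_j(t')\,
#'   e^{-(t-t')/\tau_{out}}\,dt',}
#' mimicking the relatively slow response of real muscles.
#'
#' @param state A [network_state()].
#' @param s Student rates.
#' @param tau_out Output smoothing timescale in seconds (default 25 ms).
#' @return A [signal()] with one row per output channel.
#' @export
motor_output <- function(state, s, tau_out = 0.025) {
  sf <- exp_filter(s, tau_out, normalized = FALSE)
  signal(state$M %*% sf$values, s$grid, units = "")
}

#' Motor error projected onto student neurons
#'
#' \deqn{\epsilon_j(t) = \sum_a M_{aj} (y_a(t) - \bar y_a(t)).}
#' This is the per-student-neuron error signal an ideal tutor must integrate;
#' it requires knowing the student-to-output assignment `M` (credit
#' assignment).
#'
#' @param state A [network_state()] (its `M` is used; pass a scrambled copy to
#'   model credit mis-assignment).
#' @param y Current motor output.
#' @param y_target Target output on the same grid.
#' @return A [signal()] with one row per student neuron.
#' @export
motor_error <- function(state, y, y_target) {
  check_same_grid(y, y_target)
  if (nrow(y$values) != nrow(state$M)) {
    stop("output channels do not match nrow(M)", call. = FALSE)
  }
  signal(crossprod(state$M, y$values - y_target$values), y$grid, units = "")
}

#' Quadratic loss between output and target
#'
#' \deqn{L = \frac12 \sum_a \int_0^T [y_a(t) - \bar y_a(t)]^2\,dt,}
#' computed by trapezoid quadrature on the grid.
#'
#' @param y,y_target Signals on the same grid with equal channel counts.
#' @return Scalar loss (>= 0, zero iff the traces coincide on the grid).
#' @seealso [motor_rms()] for the normalized per-sample error.
#' @export
motor_loss <- function(y, y_target) {
  check_same_grid(y, y_target)
  d2 <- (y$values - y_target$values)^2
  0.5 * sum(d2 %*% trapz_weights(y$grid$n, y$grid$dt))
}

#' Root-mean-square motor error
#'
#' Per-sample RMS mismatch between output and target, a normalized companion
#' to [motor_loss()] convenient for plotting learning curves.
#'
#' @inheritParams motor_loss
#' @return Scalar RMS error.
#' @export
motor_rms <- function(y, y_target) {
  check_same_grid(y, y_target)
  sqrt(mean((y$values - y_target$values)^2))
}

check_same_grid <- function(a, b) {
  ga <- a$grid; gb <- b$grid
  if (ga$n != gb$n || abs(ga$dt - gb$dt) > 1e-12 ||
      abs(ga$t_start - gb$t_start) > 1e-12) {
    stop("signals are not on the same time grid", call. = FALSE)
  }
  if (nrow(a$values) != nrow(b$values)) {
    stop("signals have different channel counts", call. = FALSE)
  }
  invisible(TRUE)
}

#' Specification of a smooth random target output
#'
#' Targets emulate recordings of air-sac pressure during song: smooth traces
#' of roughly 1 s duration with characteristic timescale of tens of
#' milliseconds, but otherwise arbitrary. Channels are independent white
#' noise passed twice through a causal exponential filter (each stage
#' `tau_smooth / 2`, so the autocorrelation time is close to `tau_smooth`),
#' then mapped affinely into the amplitude range.
#'
#' @param n_channels Number of output channels (default 2).
#' @param tau_smooth Smoothness timescale in seconds (default 0.05).
#' @param amplitude Length-2 numeric range the trace is scaled into.
#' @param onset_ramp If `TRUE` (default) the trace rises smoothly from zero
#'   at the start of the program (timescale `tau_smooth`), the way pressure
#'   traces rise from the expiratory baseline at motif onset; the smoothed
#'   motor output of the model likewise starts from rest, so targets without
#'   the ramp carry an unlearnable mismatch in the first tens of ms.
#' @return An object of class `"target_spec"`.
#' @export
target_spec <- function(n_channels = 2, tau_smooth = 0.05,
                        amplitude = c(0, 1), onset_ramp = TRUE) {
  if (tau_smooth <= 0) stop("`tau_smooth` must be positive", call. = FALSE)
  structure(list(n_channels = n_channels, tau_smooth = tau_smooth,
                 amplitude = amplitude, onset_ramp = onset_ramp),
            class = "target_spec")
}

#' Generate a smooth random target
#'
#' Deterministic given the RNG state; call `set.seed()` first (the experiment
#' drivers do this from their config seed).
#'
#' @param spec A [target_spec()].
#' @param grid A [time_grid()].
#' @return A [signal()] with `spec$n_channels` rows, each within the amplitude
#'   range.
#' @export
generate_target <- function(spec, grid) {
  # lead-in so the filter transient is discarded
  lead <- ceiling(5 * spec$tau_smooth / grid$dt)
  n_tot <- grid$n + lead
  noise <- matrix(rnorm(spec$n_channels * n_tot), spec$n_channels, n_tot)
  sm <- .expfilt_mat(noise, grid$dt, spec$tau_smooth / 2, TRUE, 0)
  sm <- .expfilt_mat(sm, grid$dt, spec$tau_smooth / 2, TRUE, 0)
  sm <- sm[, (lead + 1):n_tot, drop = FALSE]
  lo <- spec$amplitude[1]; hi <- spec$amplitude[2]
  for (ch in seq_len(nrow(sm))) {
    rng <- range(sm[ch, ])
    if (diff(rng) < .Machine$double.eps) {
      sm[ch, ] <- (lo + hi) / 2
    } else {
      sm[ch, ] <- lo + (hi - lo) * (sm[ch, ] - rng[1]) / diff(rng)
    }
  }
  if (isTRUE(spec$onset_ramp)) {
    env <- 1 - exp(-(grid$times - grid$t_start) / spec$tau_smooth)
    sm <- sweep(sm, 2, env, `*`)
  }
  signal(sm, grid, units = "")
}
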