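#' Parameters of the two-timescale heterosynaptic plasticity rule
#'
#' The conductor-student synapse changes according to
#' \deqn{dW_{ij}/dt = \eta\,\tilde c_i(t)\,(g_j(t) - \theta),}
#' where \eqn{\tilde c_i = K * c_i} is the conductor rate filtered with the
#' double-exponential kernel \eqn{K(t) = \alpha K_1(t) - \beta K_2(t)},
#' \eqn{K_i(t) = \tau_i^{-1} e^{-t/\tau_i}} for \eqn{t \ge 0}. The pair
#' \eqn{(\alpha, \beta)} interpolates between purely rate-based plasticity
#' (one of them zero) and timing-based plasticity (\eqn{\alpha/\beta \approx
#' 1}); the overall scale is absorbed into the learning rate, so
#' \eqn{\alpha - \beta = 1} is enforced by convention (override with
#' `enforce_normalization = FALSE` for exploratory use).
#'
#' @param alpha,beta Dimensionless kernel coefficients.
#' @param tau1,tau2 Kernel timescales in seconds (defaults 80 ms and 40 ms).
#' @param eta Learning rate per rendition.
#' @param theta Tutor firing-rate threshold in Hz (default 80).
#' @param enforce_normalization Require `alpha - beta == 1` (default `TRUE`).
#' @return An object of class `"plasticity_params"`.
#' @examples
#' p <- plasticity_params(alpha = 1, beta = 0)
#' optimal_timescale(p) # 0.08 s
#' @export
plasticity_params <- function(alpha, beta, tau1 = 0.08, tau2 = 0.04,
                              eta = 0.05, theta = 80,
                              enforce_normalization = TRUE) {
  if (tau1 <= 0 || tau2 <= 0) stop("timescales must be positive",
                                   call. = FALSE)
  if (eta < 0) stop("`eta` must be non-negative", call. = FALSE)
  if (enforce_normalization && abs(alpha - beta - 1) > 1e-9) {
    stop("convention alpha - beta = 1 violated; set ",
         "`enforce_normalization = FALSE` to override", call. = FALSE)
  }
  structure(list(alpha = alpha, beta = beta, tau1 = tau1, tau2 = tau2,
                 eta = eta, theta = theta),
            class = "plasticity_params")
}

#' @export
print.plasticity_params <- function(x, ...) {
  cat(sprintf(paste0("<plasticity_params> alpha = %g, beta = %g, tau1 = %g s,",
                     " tau2 = %g s, eta = %g, theta = %g Hz\n"),
              x$alpha, x$beta, x$tau1, x$tau2, x$eta, x$theta))
  invisible(x)
}

#' Plasticity kernel K(t)
#'
#' Causal double-exponential kernel \eqn{K(t) = \alpha \tau_1^{-1}
#' e^{-t/\tau_1} - \beta \tau_2^{-1} e^{-t/\tau_2}} for `t >= 0`, zero for
#' `t < 0`. It integrates to \eqn{\alpha - \beta} and has first moment
#' \eqn{\alpha\tau_1 - \beta\tau_2}.
#'
#' @param t Times in seconds (vectorized).
#' @param params A [plasticity_params()].
#' @return Kernel values.
#' @export
plasticity_kernel <- function(t, params) {
  k <- ifelse(t >= 0,
              params$alpha / params$tau1 * exp(-t / params$tau1) -
                params$beta / params$tau2 * exp(-t / params$tau2),
              0)
  as.numeric(k)
}

#' Conductor rates filtered with the plasticity kernel
#'
#' Computes \eqn{\tilde c_i = K * c_i} (causal convolution on the grid) as the
#' difference of the two normalized exponential filters.
#'
#' @param c_sig Conductor rate [signal()].
#' @param params A [plasticity_params()].
#' @return A [signal()] of the same shape.
#' @export
filter_conductor <- function(c_sig, params) {
  f1 <- exp_filter(c_sig, params$tau1, normalized = TRUE)
  f2 <- exp_filter(c_sig, params$tau2, normalized = TRUE)
  signal(params$alpha * f1$values - params$beta * f2$values, c_sig$grid,
         units = c_sig$units)
}

#' Per-rendition weight update of the heterosynaptic rule
#'
#' Accumulates the plasticity rule over one rendition of the motor program:
#' \deqn{\Delta W_{ij} = \eta \int_0^T \tilde c_i(t)\,(g_j(t) - \theta)\,dt,}
#' and returns the updated weight matrix. With `positivity = TRUE` the result
#' is clipped at zero elementwise after the update (synapses cannot change
#' sign), as appropriate for the spiking model.
#'
#' @param W Current weights, `n_conductor x n_student`.
#' @param c_filtered Kernel-filtered conductor rates ([filter_conductor()]).
#' @param g Tutor signal, one row per student neuron.
#' @param params A [plasticity_params()].
#' @param positivity Clip updated weights at zero (default `FALSE`).
#' @return Updated weight matrix.
#' @export
weight_update <- function(W, c_filtered, g, params, positivity = FALSE) {
  if (nrow(c_filtered$values) != nrow(W) || nrow(g$values) != ncol(W)) {
    stop("signal dimensions do not match W", call. = FALSE)
  }
  check_same_grid_loose(c_filtered, g)
  wts <- trapz_weights(c_filtered$grid$n, c_filtered$grid$dt)
  dW <- params$eta *
    (c_filtered$values %*% (wts * t(g$values - params$theta)))
  W <- W + dW
  if (positivity) W[W < 0] <- 0
  W
}

check_same_grid_loose <- function(a, b) {
  if (a$grid$n != b$grid$n || abs(a$grid$dt - b$grid$dt) > 1e-12) {
    stop("signals are not on the same time grid", call. = FALSE)
  }
  invisible(TRUE)
}

#' Optimal tutor error-integration timescale
#'
#' For the double-exponential plasticity kernel, learning follows the loss
#' gradient when the tutor integrates the motor error on the timescale
#' \deqn{\tau^*_{tutor} = \frac{\alpha\tau_1 - \beta\tau_2}{\alpha - \beta}.}
#'
#' @param params A [plasticity_params()].
#' @return Timescale in seconds.
#' @examples
#' optimal_timescale(plasticity_params(0, -1)) # 0.04 s
#' optimal_timescale(plasticity_params(24, 23)) # 1 s
#' @export
optimal_timescale <- function(params) {
  d <- params$alpha - params$beta
  if (abs(d) < .Machine$double.eps) {
    stop("alpha = beta: optimal timescale is undefined", call. = FALSE)
  }
  (params$alpha * params$tau1 - params$beta * params$tau2) / d
}
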