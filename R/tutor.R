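#' Tutor signal specification
#'
#' Describes how the guiding signal `g_j(t)` is produced. Three modes are
#' supported: `"matched"` - the ideal tutor that integrates the motor error
#' over the recent past with timescale `tau_tutor`; `"saturating"` - the same
#' integral passed through a tanh nonlinearity bounding rates to
#' `[theta - rho, theta + rho]`; `"reinforcement"` - a tutor that has no
#' access to the motor error and instead learns its firing-rate program from
#' a scalar reward signal (see [reinforcement_update()]).
#'
#' @param mode One of `"matched"`, `"saturating"`, `"reinforcement"`.
#' @param tau_tutor Error-integration / memory timescale in seconds. Use
#'   [optimal_timescale()] for a matched tutor; 0 selects the memory-less
#'   reinforcement rule.
#' @param zeta Tutor gain (the ratio of the gradient-descent rate to the
#'   plasticity rate; sets how strongly integrated error deflects the rate).
#' @param rho Saturation half-range in Hz (default 80, so rates stay in
#'   0-160 Hz with the default threshold).
#' @param theta Baseline/threshold firing rate in Hz (default 80, shared with
#'   the plasticity threshold).
#' @param eta_tutor Learning rate of the reinforcement tutor (in Hz of rate
#'   change per unit normalized reward deviation per unit fluctuation, when
#'   `reward_norm` is enabled).
#' @param reward_norm If `TRUE` the reward deviation `R - Rbar` is
#'   divided by a running estimate of its own scale before entering the
#'   tutor update, making the tutor step invariant to the overall reward
#'   magnitude. Off by default: the shrinking of raw reward deviations as
#'   learning proceeds anneals the tutor step and stabilizes the trained
#'   state.
#' @param explore_sd Exploration noise s.d. in Hz used by the rate-engine
#'   reinforcement tutor (spiking engines get exploration from Poisson
#'   variability instead).
#' @param explore_tau Smoothing timescale of the exploration noise in seconds.
#' @return An object of class `"tutor_spec"`.
#' @export
tutor_spec <- function(mode = c("matched", "saturating", "reinforcement"),
                       tau_tutor = 0.08, zeta = 1, rho = 80, theta = 80,
                       eta_tutor = 1e-3, explore_sd = 20, explore_tau = 0.02,
                       reward_norm = FALSE) {
  mode <- match.arg(mode)
  if (tau_tutor < 0) stop("`tau_tutor` must be >= 0", call. = FALSE)
  if (mode != "reinforcement" && tau_tutor == 0) {
    stop("`tau_tutor` must be positive outside reinforcement mode",
         call. = FALSE)
  }
  if (mode == "saturating" && rho <= 0) {
    stop("`rho` must be positive in saturating mode", call. = FALSE)
  }
  structure(list(mode = mode, tau_tutor = tau_tutor, zeta = zeta, rho = rho,
                 theta = theta, eta_tutor = eta_tutor,
                 explore_sd = explore_sd, explore_tau = explore_tau,
                 reward_norm = reward_norm),
            class = "tutor_spec")
}

#' @export
print.tutor_spec <- function(x, ...) {
  cat(sprintf(paste0("<tutor_spec> mode = %s, tau_tutor = %g s, zeta = %g, ",
                     "rho = %g Hz, theta = %g Hz\n"),
              x$mode, x$tau_tutor, x$zeta, x$rho, x$theta))
  invisible(x)
}

#' Matched tutor signal
#'
#' The tutor signal that drives gradient-descent learning for the
#' heterosynaptic plasticity rule integrates the motor error over the recent
#' past:
#' \deqn{g_j(t) = \theta - \frac{\zeta}{\alpha-\beta}\,
#'   \frac{1}{\tau_{tutor}} \int_0^t \epsilon_j(t')\,
#'   e^{-(t-t')/\tau_{tutor}}\,dt'.}
#' Matching requires `spec$tau_tutor == optimal_timescale(params)`, but any
#' positive timescale can be evaluated (that is how mismatch is studied).
#'
#' @param eps Motor error [signal()], one row per student neuron
#'   ([motor_error()]).
#' @param spec A [tutor_spec()].
#' @param params A [plasticity_params()] (supplies `alpha - beta`).
#' @return Tutor rate [signal()] in Hz.
#' @export
matched_tutor <- function(eps, spec, params) {
  d <- params$alpha - params$beta
  if (abs(d) < .Machine$double.eps) {
    stop("alpha = beta: matched tutor undefined", call. = FALSE)
  }
  integ <- exp_filter(eps, spec$tau_tutor, normalized = TRUE)
  signal(spec$theta - (spec$zeta / d) * integ$values, eps$grid, units = "Hz")
}

#' Saturating tutor signal
#'
#' Same error integral as [matched_tutor()], passed through a sigmoidal
#' nonlinearity that models the bounded firing range of real neurons:
#' \deqn{\tilde g_j(t) = \theta - \rho \tanh\!\left[\frac{\zeta}{
#'   \rho(\alpha-\beta)\tau_{tutor}} \int_0^t \epsilon_j(t')\,
#'   e^{-(t-t')/\tau_{tutor}}\,dt'\right],}
#' so outputs lie in \eqn{[\theta-\rho, \theta+\rho]} (0-160 Hz for the
#' default `theta = rho = 80` Hz).
#'
#' @inheritParams matched_tutor
#' @return Tutor rate [signal()] in Hz, bounded by `theta +/- rho`.
#' @export
saturating_tutor <- function(eps, spec, params) {
  d <- params$alpha - params$beta
  if (abs(d) < .Machine$double.eps) {
    stop("alpha = beta: matched tutor undefined", call. = FALSE)
  }
  if (spec$rho <= 0) stop("`rho` must be positive", call. = FALSE)
  integ <- exp_filter(eps, spec$tau_tutor, normalized = TRUE)
  arg <- (spec$zeta / d) * integ$values / spec$rho
  signal(spec$theta - spec$rho * tanh(arg), eps$grid, units = "Hz")
}

#' Instantaneous reward from the output mismatch
#'
#' The reinforcement tutor only sees a scalar reward trace. The packaged
#' choice is the negative instantaneous squared error,
#' \deqn{R(t) = -\sum_a (y_a(t) - \bar y_a(t))^2,}
#' which is maximal (zero) at a perfect match, monotone in goodness-of-match
#' at every time, and integrates to \eqn{-2L} with the quadratic loss. Any
#' bounded monotone transform would serve.
#'
#' @inheritParams motor_loss
#' @return Single-channel reward [signal()].
#' @export
reward_from_loss <- function(y, y_target) {
  check_same_grid(y, y_target)
  r <- -colSums((y$values - y_target$values)^2)
  signal(matrix(r, 1), y$grid, units = "")
}

#' State of the reinforcement-learning tutor
#'
#' Carries the tutor firing-rate program `f`, the rendition-averaged tutor
#' activity `g_bar` (exponentially decaying average, one e-fold per five
#' renditions) and the reward baseline `r_bar_init` (the terminal reward of
#' the previous rendition, which seeds the within-rendition exponential
#' average of the reward). Construct it from the first rendition with
#' [reinforcement_init()].
#'
#' @param f Tutor rate program [signal()] (rows = student neurons), clipped
#'   at 0.
#' @param g_bar Baseline mean tutor activity, same shape as `f`.
#' @param r_bar_init Scalar reward baseline carried across renditions.
#' @param r_scale Running scale (RMS) of reward deviations, used by the
#'   normalized update; `NA` until measured.
#' @return An object of class `"reinforcement_state"`.
#' @export
reinforcement_state <- function(f, g_bar, r_bar_init, r_scale = NA_real_) {
  stopifnot(inherits(f, "signal"), inherits(g_bar, "signal"))
  if (!identical(dim(f$values), dim(g_bar$values))) {
    stop("`f` and `g_bar` must have the same shape", call. = FALSE)
  }
  f$values[f$values < 0] <- 0
  structure(list(f = f, g_bar = g_bar, r_bar_init = r_bar_init,
                 r_scale = r_scale),
            class = "reinforcement_state")
}

#' Initialize the reinforcement tutor from the first rendition
#'
#' The activity baseline starts at the first rendition's tutor activity and
#' the reward baseline at its terminal reward, so no state is undefined when
#' updates begin on the second rendition.
#'
#' @param f Initial tutor rate program (e.g. constant `theta`).
#' @param g_first Tutor activity of the first rendition.
#' @param reward_first Reward signal of the first rendition.
#' @return A [reinforcement_state()].
#' @export
reinforcement_init <- function(f, g_first, reward_first) {
  reinforcement_state(f, g_first,
                      reward_first$values[1, ncol(reward_first$values)])
}

#' Reward-driven update of the tutor rate program
#'
#' Implements the node-perturbation-style rule by which the tutor discovers
#' its corrective signal from reward alone. With the rendition's activity
#' fluctuation \eqn{\xi_j(t) = g_j(t) - \bar g_j(t)} and the reward deviation
#' from baseline, the rate program changes as
#' \deqn{\Delta f_j(t) = \eta_{tutor} (R(t) - \bar R(t))\,\xi_j(t)}
#' for the memory-less tutor (`tau_tutor = 0`), or its causal exponential
#' filtering over the tutor memory timescale for `tau_tutor > 0`. Rates are
#' clipped at zero. The reward baseline \eqn{\bar R(t)} is the exponential
#' average of `R` (timescale 1 s) seeded with the previous rendition's
#' terminal reward; the activity baseline decays by one e-fold every five
#' renditions. Fluctuations that increase reward are thereby "frozen into"
#' the rate program for subsequent renditions.
#'
#' @param state A [reinforcement_state()].
#' @param g_actual Tutor activity realized on the just-completed rendition.
#' @param reward Reward [signal()] of that rendition ([reward_from_loss()]).
#' @param spec A [tutor_spec()] (uses `eta_tutor` and `tau_tutor`).
#' @param r_smooth_tau Timescale of the within-rendition reward average in
#'   seconds (default 1).
#' @param g_bar_efold Renditions per e-fold of the activity-baseline decay
#'   (default 5).
#' @return The updated [reinforcement_state()].
#' @export
reinforcement_update <- function(state, g_actual, reward, spec,
                                 r_smooth_tau = 1, g_bar_efold = 5) {
  check_same_grid_loose(g_actual, reward)
  check_same_grid_loose(g_actual, state$f)
  r_bar <- exp_filter(reward, r_smooth_tau, normalized = TRUE,
                      init = state$r_bar_init)
  rdev <- as.numeric(reward$values - r_bar$values)
  lambda <- exp(-1 / g_bar_efold)
  r_scale <- state$r_scale
  if (isTRUE(spec$reward_norm)) {
    rms <- sqrt(mean(rdev^2))
    r_scale <- if (is.na(r_scale)) rms else {
      lambda * r_scale + (1 - lambda) * rms
    }
    rdev <- rdev / max(r_scale, .Machine$double.eps)
  }
  xi <- g_actual$values - state$g_bar$values
  dev <- sweep(xi, 2, rdev, `*`)
  if (spec$tau_tutor > 0) {
    dev <- .expfilt_mat(dev, g_actual$grid$dt, spec$tau_tutor, TRUE, 0)
  }
  f_new <- state$f$values + spec$eta_tutor * dev
  f_new[f_new < 0] <- 0
  g_bar_new <- lambda * state$g_bar$values + (1 - lambda) * g_actual$values
  reinforcement_state(
    signal(f_new, state$f$grid, units = "Hz"),
    signal(g_bar_new, state$g_bar$grid, units = "Hz"),
    reward$values[1, ncol(reward$values)],
    r_scale = r_scale
  )
}
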