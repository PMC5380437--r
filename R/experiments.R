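#' Configuration for a rate-based learning run
#'
#' Bundles everything a rate-engine experiment needs: network sizes, program
#' duration, plasticity rule, tutor specification and target generator. With
#' `tutor = NULL` a matched tutor is built automatically, with
#' `tau_tutor = optimal_timescale(plasticity)`. All defaults are the
#' representative desk-scale conditions used throughout the package: a 1 s
#' program on a 1 ms grid, 100 conductor and 20 student neurons, two output
#' channels, and learning rates tuned so matched learning converges within
#' 1000 renditions.
#'
#' @param seed Integer seed fixed before any stochastic operation.
#' @param renditions Number of learning cycles.
#' @param t_end Program duration in seconds.
#' @param dt Grid step in seconds (default 1 ms).
#' @param n_conductor,n_student,n_channels Network sizes.
#' @param plasticity A [plasticity_params()].
#' @param tutor A [tutor_spec()] or `NULL` for the matched tutor.
#' @param target A [target_spec()] (its channel count must match
#'   `n_channels`).
#' @param w Tutor-to-student gain in the student activity.
#' @param tau_out Motor-output smoothing timescale in seconds.
#' @param positivity Constrain conductor-student weights to be non-negative.
#' @param w_init_max Initial weights are uniform on `[0, w_init_max]`.
#' @param zeta Tutor gain used when `tutor = NULL`.
#' @param scramble_rho Fraction of student neurons whose output-channel
#'   assignment the tutor gets wrong (see [run_credit_scramble()]).
#' @param checkpoint_every Snapshot interval in renditions (`Inf` for none).
#' @return An object of class `"run_config"`.
#' @export
rate_config <- function(seed = 1, renditions = 1000, t_end = 1, dt = 1e-3,
                        n_conductor = 100, n_student = 20, n_channels = 2,
                        plasticity = plasticity_params(0, -1, eta = 16),
                        tutor = NULL,
                        target = target_spec(n_channels = n_channels),
                        w = 0.5, tau_out = 0.025, positivity = FALSE,
                        w_init_max = 0.1, zeta = 200, scramble_rho = 0,
                        checkpoint_every = Inf) {
  if (is.null(tutor)) {
    tutor <- tutor_spec("matched", tau_tutor = optimal_timescale(plasticity),
                        zeta = zeta)
  }
  if (target$n_channels != n_channels) {
    stop("target channel count must match `n_channels`", call. = FALSE)
  }
  structure(list(engine = "rate", seed = as.integer(seed),
                 renditions = renditions, t_end = t_end, dt = dt,
                 n_conductor = n_conductor, n_student = n_student,
                 n_channels = n_channels, plasticity = plasticity,
                 tutor = tutor, target = target, w = w, tau_out = tau_out,
                 positivity = positivity, w_init_max = w_init_max,
                 scramble_rho = scramble_rho,
                 checkpoint_every = checkpoint_every),
            class = "run_config")
}

#' Configuration for a spiking learning run
#'
#' Like [rate_config()] but for the leaky integrate-and-fire engine. The
#' default network is a reduced version of the full songbird-calibrated
#' model (150 conductor and 40 student neurons instead of 300 and 80) with
#' synaptic density preserved and synaptic strengths rescaled to compensate
#' the thinner conductor population, which keeps a full learning run
#' tractable on a desktop; pass a full-size [spiking_params()] to override. With `target_amplitude = NULL` the target
#' range is calibrated from an untrained baseline rendition so that targets
#' are reachable by the network.
#'
#' @inheritParams rate_config
#' @param spiking A [spiking_params()]; `NULL` builds the reduced network.
#' @param target_amplitude Length-2 range for the target, or `NULL` to
#'   calibrate from the untrained network output.
#' @param w_scale Multiplier applied to `w_mean`/`w_sd` when building the
#'   reduced network, compensating the thinner conductor population.
#' @return An object of class `"run_config"`.
#' @export
spiking_config <- function(seed = 1, renditions = 600, t_end = 1,
                           n_channels = 2,
                           plasticity = plasticity_params(1, 0, eta = 4e-3),
                           tutor = NULL, spiking = NULL,
                           target = NULL, target_amplitude = NULL,
                           tau_out = 0.025, zeta = 1200, w_scale = 2,
                           scramble_rho = 0, checkpoint_every = Inf) {
  if (is.null(spiking)) {
    spiking <- spiking_params(n_conductor = 150, n_student = 40,
                              synapses_per_student = 74,
                              w_mean = 32.6 * w_scale, w_sd = 17.4 * w_scale)
  }
  if (is.null(tutor)) {
    tutor <- tutor_spec("saturating",
                        tau_tutor = optimal_timescale(plasticity),
                        zeta = zeta)
  }
  if (is.null(target)) {
    target <- target_spec(n_channels = n_channels)
  }
  structure(list(engine = "spiking", seed = as.integer(seed),
                 renditions = renditions, t_end = t_end, dt = 1e-3,
                 n_channels = n_channels, plasticity = plasticity,
                 tutor = tutor, spiking = spiking, target = target,
                 target_amplitude = target_amplitude, tau_out = tau_out,
                 scramble_rho = scramble_rho,
                 checkpoint_every = checkpoint_every),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("<run_config> engine = %s, seed = %d, %d renditions\n",
              x$engine, x$seed, x$renditions))
  invisible(x)
}

#' Run a full learning experiment
#'
#' Executes the complete learning loop - generate conductor activity, drive
#' the student, read out the motor output, evaluate the error, produce the
#' tutor signal, and apply the heterosynaptic weight update - once per
#' rendition, with the engine (rate or spiking) selected by the config. In
#' the rate engine the error-integrating tutor runs in closed loop within
#' each rendition; in the spiking engine the tutor rate program is set from
#' the previous rendition's motor error (the first rendition runs at the
#' tutor baseline `theta`). Runs whose loss exceeds 1000x the initial loss
#' abort early and are flagged, keeping the partial trace.
#'
#' @param config A [rate_config()] or [spiking_config()].
#' @return A `"learning_trace"`: list with per-rendition `loss` and `rms`,
#'   `initial_loss`, `final_loss`, `aborted`, weight/output `snapshots`
#'   (when checkpointing is enabled), and the complete `config` (including
#'   the seed), from which the run can be reproduced exactly.
#' @export
run_matched <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (config$engine == "rate") {
    run_rate_engine(config)
  } else {
    run_spiking_engine(config)
  }
}

#' Tutor-student mismatch sweep
#'
#' Re-runs matched-style learning over a grid of plasticity rules (varying
#' `alpha` with `beta = alpha - 1`, so each rule implies its own optimal
#' timescale) against a grid of imposed tutor timescales, with several seeds
#' per cell. Diagonal cells (`tau_tutor` equal to the implied optimum) learn
#' efficiently; cells far below the diagonal disrupt learning and cells
#' above it learn more slowly. Per-cell failures are recorded and the sweep
#' continues.
#'
#' @param config Base [rate_config()]; its plasticity `eta`, tutor gain and
#'   network sizes are reused for every cell.
#' @param alpha Vector of kernel coefficients (with `beta = alpha - 1`).
#' @param tau_tutor Vector of imposed tutor timescales in seconds.
#' @param renditions Learning cycles per cell.
#' @param seeds Vector of seeds run per cell (median reported).
#' @return A `"sweep_result"`: arrays `final` and `initial` of dimension
#'   `length(alpha) x length(tau_tutor) x length(seeds)`, the implied
#'   `tau_star` per row, and matrices of per-cell medians.
#' @export
run_mismatch_sweep <- function(config,
                               alpha = c(0, 1, 3, 9, 24),
                               tau_tutor = c(0.04, 0.08, 0.16, 0.4, 1),
                               renditions = 200, seeds = 1:3) {
  stopifnot(inherits(config, "run_config"), config$engine == "rate")
  na <- length(alpha); nt <- length(tau_tutor); nseed <- length(seeds)
  final <- array(NA_real_, c(na, nt, nseed))
  initial <- array(NA_real_, c(na, nt, nseed))
  tau_star <- numeric(na)
  for (ia in seq_len(na)) {
    p <- plasticity_params(alpha[ia], alpha[ia] - 1,
                           tau1 = config$plasticity$tau1,
                           tau2 = config$plasticity$tau2,
                           eta = config$plasticity$eta,
                           theta = config$plasticity$theta)
    tau_star[ia] <- optimal_timescale(p)
    for (it in seq_len(nt)) {
      tut <- config$tutor
      tut$mode <- "matched"
      tut$tau_tutor <- tau_tutor[it]
      for (is in seq_len(nseed)) {
        cfg <- config
        cfg$plasticity <- p
        cfg$tutor <- tut
        cfg$renditions <- renditions
        cfg$seed <- as.integer(seeds[is])
        tr <- tryCatch(run_matched(cfg), error = function(e) NULL)
        if (!is.null(tr)) {
          initial[ia, it, is] <- tr$initial_loss
          final[ia, it, is] <- tr$final_loss
        }
      }
    }
  }
  med <- apply(final, c(1, 2), stats::median, na.rm = TRUE)
  med_init <- apply(initial, c(1, 2), stats::median, na.rm = TRUE)
  structure(list(final = final, initial = initial,
                 median_final = med, median_initial = med_init,
                 alpha = alpha, tau_star = tau_star, tau_tutor = tau_tutor,
                 seeds = seeds, renditions = renditions),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %d x %d grid, %d seed(s), %d renditions\n",
              length(x$alpha), length(x$tau_tutor), length(x$seeds),
              x$renditions))
  m <- x$median_final
  dimnames(m) <- list(paste0("tau*=", signif(x$tau_star, 3)),
                      paste0("tau=", signif(x$tau_tutor, 3)))
  print(signif(m, 3))
  invisible(x)
}

#' Learning with scrambled credit assignment
#'
#' The tutor computes the motor error with a scrambled copy of the
#' student-to-output map: a fraction `rho` of the student neurons is
#' reassigned to the wrong output channel when the error is projected, while
#' the true map still produces the output. Learning tolerates moderate
#' mis-assignment but fails as `rho` approaches 0.5, where the tutor's
#' per-channel error information vanishes.
#'
#' @param config A [rate_config()] with two output channels.
#' @param rho Fraction in `[0, 1]` of mis-assigned student neurons.
#' @return A `"learning_trace"` (see [run_matched()]).
#' @export
run_credit_scramble <- function(config, rho) {
  stopifnot(inherits(config, "run_config"))
  if (!is.numeric(rho) || rho < 0 || rho > 1) {
    stop("`rho` must lie in [0, 1]", call. = FALSE)
  }
  if (config$n_channels != 2) {
    stop("credit scrambling is defined for two output channels",
         call. = FALSE)
  }
  config$scramble_rho <- rho
  run_matched(config)
}

#' Two-stage reinforcement-driven learning
#'
#' Interleaves two learning processes: the tutor updates its firing-rate
#' program from the scalar reward ([reinforcement_update()]), while the
#' student consolidates the tutor's signal through the heterosynaptic rule.
#' The tutor starts from a flat program at `theta` and needs many renditions
#' of exploration before its signal becomes informative, so convergence is
#' much slower than with a tutor that knows the credit assignment. For the
#' spiking engine the per-rendition mean number of surviving conductor
#' inputs per student neuron is recorded (`pruning`), tracking synapse
#' elimination during consolidation.
#'
#' @param config A [rate_config()] or [spiking_config()] whose tutor mode is
#'   `"reinforcement"`.
#' @return A `"learning_trace"` with the final tutor rate program in
#'   `tutor_program` and, for the spiking engine, a per-rendition `pruning`
#'   vector (mean surviving conductor inputs per student neuron).
#' @export
run_reinforcement <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (config$tutor$mode != "reinforcement") {
    stop("config$tutor$mode must be 'reinforcement'", call. = FALSE)
  }
  if (config$engine == "rate") {
    run_rate_engine(config)
  } else {
    run_spiking_engine(config)
  }
}

#' @export
print.learning_trace <- function(x, ...) {
  cat(sprintf(paste0("<learning_trace> %s engine, %d/%d renditions%s\n",
                     "  loss: %.4g -> %.4g (rms %.4g -> %.4g)\n"),
              x$config$engine, x$renditions_run, x$config$renditions,
              if (x$aborted) " [aborted: divergence]" else "",
              x$initial_loss, x$final_loss,
              x$rms[1], x$rms[x$renditions_run]))
  invisible(x)
}

# ---- internal engines ------------------------------------------------------

scramble_map <- function(M, rho) {
  ns <- ncol(M)
  n_wrong <- round(rho * ns)
  if (n_wrong == 0) return(M)
  idx <- sample.int(ns, n_wrong)
  Ms <- M
  # two channels: swap the rows' entries for the scrambled students
  Ms[, idx] <- M[2:1, idx]
  Ms
}

new_learning_trace <- function(config, loss, rms, renditions_run, aborted,
                               snapshots, pruning = NULL) {
  structure(list(loss = loss, rms = rms,
                 initial_loss = loss[1],
                 final_loss = loss[renditions_run],
                 renditions_run = renditions_run, aborted = aborted,
                 snapshots = snapshots, pruning = pruning, config = config),
            class = "learning_trace")
}

flat_tutor_signal <- function(theta, n_student, grid) {
  signal(matrix(theta, n_student, grid$n), grid, units = "Hz")
}

# smoothed Gaussian exploration noise for the rate-engine reinforcement tutor
exploration_noise <- function(spec, n_student, grid) {
  raw <- matrix(rnorm(n_student * grid$n), n_student, grid$n)
  sm <- .expfilt_mat(raw, grid$dt, spec$explore_tau, TRUE, 0)
  # normalize to unit sd per sample (the filter attenuates white noise)
  sc <- sqrt(2 * spec$explore_tau / grid$dt)
  sm * sc * spec$explore_sd
}

run_rate_engine <- function(config) {
  set.seed(config$seed)
  p <- config$plasticity
  tut <- config$tutor
  grid <- time_grid(0, config$t_end, config$dt)
  c_sig <- generate_conductor_rates(grid, config$n_conductor)
  c_filt <- filter_conductor(c_sig, p)
  target <- generate_target(config$target, grid)
  M <- output_map(config$n_student, config$n_channels)
  W <- matrix(runif(config$n_conductor * config$n_student,
                    0, config$w_init_max),
              config$n_conductor, config$n_student)
  x_inh <- config$w * tut$theta + mean(crossprod(W, c_sig$values))
  st <- network_state(W, M, w = config$w, x_inh = x_inh)
  st_tutor <- st
  if (config$scramble_rho > 0) {
    st_tutor$M <- scramble_map(M, config$scramble_rho)
  }

  reinforcement <- tut$mode == "reinforcement"
  rl_state <- NULL
  f <- flat_tutor_signal(tut$theta, config$n_student, grid)

  nr <- config$renditions
  loss <- rep(NA_real_, nr); rms <- rep(NA_real_, nr)
  snapshots <- list()
  aborted <- FALSE
  r_done <- 0
  for (r in seq_len(nr)) {
    if (reinforcement) {
      # the reinforcement tutor plays its learned rate program plus
      # exploration noise; it has no access to the motor error
      g <- signal(pmax(f$values + exploration_noise(tut, config$n_student,
                                                    grid), 0),
                  grid, units = "Hz")
      s <- student_rates(st, c_sig, g)
      y <- motor_output(st, s, config$tau_out)
    } else {
      # error-integrating tutor runs in closed loop within the rendition:
      # the guiding signal integrates the motor error online while also
      # contributing to the student activity that shapes the output
      drive <- crossprod(st$W, c_sig$values) + config$w * tut$theta - x_inh
      res <- .rate_closed_loop(drive, M, st_tutor$M, target$values, grid$dt,
                               config$tau_out, tut$tau_tutor,
                               tut$zeta / (p$alpha - p$beta), config$w,
                               tut$theta, tut$rho,
                               tut$mode == "saturating")
      g <- signal(res$g, grid, units = "Hz")
      y <- signal(res$y, grid, units = "")
    }
    loss[r] <- motor_loss(y, target)
    rms[r] <- motor_rms(y, target)
    if (reinforcement) {
      reward <- reward_from_loss(y, target)
      if (is.null(rl_state)) {
        rl_state <- reinforcement_init(f, g, reward)
      } else {
        rl_state <- reinforcement_update(rl_state, g, reward, tut)
      }
      f <- rl_state$f
    }
    if (p$eta > 0) {
      st$W <- weight_update(st$W, c_filt, g, p, config$positivity)
    }
    r_done <- r
    if (is.finite(config$checkpoint_every) &&
        r %% config$checkpoint_every == 0) {
      snapshots[[as.character(r)]] <- list(rendition = r, W = st$W, y = y,
                                           f = if (reinforcement) f)
    }
    if (loss[r] > 1e3 * loss[1]) {
      aborted <- TRUE
      break
    }
  }
  tr <- new_learning_trace(config, loss[seq_len(r_done)], rms[seq_len(r_done)],
                           r_done, aborted, snapshots)
  if (reinforcement) tr$tutor_program <- f
  tr
}

run_spiking_engine <- function(config) {
  set.seed(config$seed)
  p <- config$plasticity
  tut <- config$tutor
  sp <- config$spiking
  grid <- time_grid(0, config$t_end, config$dt)
  M <- output_map(sp$n_student, config$n_channels)
  W <- init_spiking_weights(sp)
  st <- network_state(W, M, positivity = TRUE)
  st_tutor <- st
  if (config$scramble_rho > 0) {
    st_tutor$M <- scramble_map(M, config$scramble_rho)
  }

  # calibrate the target range from an untrained baseline rendition so the
  # target is reachable by the network (flat tutor at theta)
  amp <- config$target_amplitude
  if (is.null(amp)) {
    y0 <- spiking_forward(W, M, flat_tutor_signal(tut$theta, sp$n_student,
                                                  grid),
                          sp, grid, config$tau_out)$y
    amp <- as.numeric(quantile(y0$values, c(0.05, 0.95)))
  }
  tspec <- config$target
  tspec$amplitude <- amp
  target <- generate_target(tspec, grid)

  reinforcement <- tut$mode == "reinforcement"
  rl_state <- NULL
  f <- flat_tutor_signal(tut$theta, sp$n_student, grid)

  nr <- config$renditions
  loss <- rep(NA_real_, nr); rms <- rep(NA_real_, nr)
  pruning <- rep(NA_real_, nr)
  snapshots <- list()
  eps_prev <- NULL
  aborted <- FALSE
  r_done <- 0
  for (r in seq_len(nr)) {
    if (!reinforcement && !is.null(eps_prev)) {
      f <- switch(tut$mode,
                  matched = matched_tutor(eps_prev, tut, p),
                  saturating = saturating_tutor(eps_prev, tut, p))
      f$values[f$values < 0] <- 0
    }
    fw <- spiking_forward(W, M, f, sp, grid, config$tau_out)
    loss[r] <- motor_loss(fw$y, target)
    rms[r] <- motor_rms(fw$y, target)
    st_tutor$W <- W
    eps_prev <- motor_error(st_tutor, fw$y, target)
    if (reinforcement) {
      reward <- reward_from_loss(fw$y, target)
      if (is.null(rl_state)) {
        rl_state <- reinforcement_init(f, fw$g_est, reward)
      } else {
        rl_state <- reinforcement_update(rl_state, fw$g_est, reward, tut)
      }
      f <- rl_state$f
    }
    if (p$eta > 0) {
      c_filt <- filter_conductor(fw$c_est, p)
      W <- weight_update(W, c_filt, fw$g_est, p, positivity = TRUE)
    }
    pruning[r] <- mean_inputs_per_student(W)
    r_done <- r
    if (is.finite(config$checkpoint_every) &&
        r %% config$checkpoint_every == 0) {
      snapshots[[as.character(r)]] <- list(rendition = r, W = W, y = fw$y,
                                           f = if (reinforcement) f)
    }
    if (loss[r] > 1e3 * loss[1]) {
      aborted <- TRUE
      break
    }
  }
  tr <- new_learning_trace(config, loss[seq_len(r_done)],
                           rms[seq_len(r_done)], r_done, aborted, snapshots,
                           pruning = pruning[seq_len(r_done)])
  if (reinforcement) tr$tutor_program <- f
  tr
}

# one spiking rendition: conductor + tutor spikes -> student spikes -> output
spiking_forward <- function(W, M, f, sp, grid, tau_out) {
  cond <- generate_conductor_spikes(grid, sp, jitter = TRUE)
  tut_spk <- generate_poisson_tutor(f)
  sim <- simulate_lif(cond, tut_spk, W, sp, t_end = grid$t_end)
  s_est <- estimate_rates(sim$spikes, sp$tau_est, grid)
  y <- signal(M %*% exp_filter(s_est, tau_out, normalized = FALSE)$values,
              grid, units = "")
  c_est <- estimate_rates(cond, sp$tau_est, grid)
  g_est <- estimate_rates(tut_spk, sp$tau_est, grid)
  list(y = y, s_est = s_est, c_est = c_est, g_est = g_est,
       spikes = sim$spikes, cond = cond)
}
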