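#' Parameters of the spiking student network
#'
#' Leaky integrate-and-fire student neurons with current-based AMPA/NMDA
#' synapses, voltage-dependent NMDA gating, and global activity-dependent
#' inhibition. Defaults are the constants used to reproduce songbird-RA-like
#' firing statistics. Synaptic currents are expressed in pA: with the 353
#' MOhm input resistance the mean 32.6 pA conductor synapse depolarizes by
#' about 11.5 mV, the scale seen in slice recordings of HVC-RA synapses.
#'
#' @param n_conductor,n_student Population sizes (defaults 300 and 80).
#' @param v_reset Reset/rest potential, mV (-72.3).
#' @param v_thresh Spike threshold, mV (-48.6).
#' @param tau_m Membrane time constant, s (24.5 ms).
#' @param tau_ref Refractory period, s (1.1 ms).
#' @param r_in Input resistance, MOhm (353).
#' @param tau_ampa,tau_nmda Synaptic current time constants, s (6.3 ms and
#'   81.5 ms).
#' @param frac_nmda Fraction of the tutor synapse carried by NMDA receptors
#'   (0.9).
#' @param w_tutor Tutor synapse strength, pA (100).
#' @param g_inh Strength of global inhibition, mV (1.80).
#' @param tau_inh Time constant of global inhibition, s (20 ms).
#' @param mg Extracellular magnesium concentration, mM (default 1), entering
#'   the NMDA gating factor [nmda_gating()].
#' @param synapses_per_student Number of conductor synapses per student
#'   neuron (148).
#' @param w_mean,w_sd Mean and s.d. of the initial conductor-student synaptic
#'   strengths, pA (32.6 and 17.4; log-normal distribution).
#' @param burst_rate Conductor firing rate during bursts, Hz (632).
#' @param burst_spikes Range of spikes per conductor burst (5-6).
#' @param jitter_onset Half-range of the uniform burst-onset jitter, s
#'   (0.3 ms).
#' @param jitter_spike Half-range of the uniform per-spike jitter, s (0.2 ms).
#' @param dt Integration step, s (default 0.1 ms; spiking events and
#'   sub-millisecond jitter need sub-ms resolution).
#' @param tau_est Timescale of the exponential kernel used to estimate rates
#'   from spike trains, s (default 20 ms; the plasticity rule and the burst
#'   detector share this estimator, range 5-40 ms).
#' @return An object of class `"spiking_params"`.
#' @export
spiking_params <- function(n_conductor = 300, n_student = 80,
                           v_reset = -72.3, v_thresh = -48.6,
                           tau_m = 24.5e-3, tau_ref = 1.1e-3, r_in = 353,
                           tau_ampa = 6.3e-3, tau_nmda = 81.5e-3,
                           frac_nmda = 0.9, w_tutor = 100,
                           g_inh = 1.80, tau_inh = 20e-3, mg = 1,
                           synapses_per_student = 148,
                           w_mean = 32.6, w_sd = 17.4,
                           burst_rate = 632, burst_spikes = c(5, 6),
                           jitter_onset = 0.3e-3, jitter_spike = 0.2e-3,
                           dt = 1e-4, tau_est = 20e-3) {
  stopifnot(tau_m > 0, tau_ref > 0, tau_ampa > 0, tau_nmda > 0, tau_inh > 0,
            dt > 0, v_thresh > v_reset, frac_nmda >= 0, frac_nmda <= 1)
  structure(list(n_conductor = n_conductor, n_student = n_student,
                 v_reset = v_reset, v_thresh = v_thresh, tau_m = tau_m,
                 tau_ref = tau_ref, r_in = r_in, tau_ampa = tau_ampa,
                 tau_nmda = tau_nmda, frac_nmda = frac_nmda,
                 w_tutor = w_tutor, g_inh = g_inh, tau_inh = tau_inh,
                 mg = mg, synapses_per_student = synapses_per_student,
                 w_mean = w_mean, w_sd = w_sd, burst_rate = burst_rate,
                 burst_spikes = burst_spikes, jitter_onset = jitter_onset,
                 jitter_spike = jitter_spike, dt = dt, tau_est = tau_est),
            class = "spiking_params")
}

#' @export
print.spiking_params <- function(x, ...) {
  cat(sprintf(paste0("<spiking_params> %d conductor, %d student; ",
                     "V_R = %g mV, V_th = %g mV, tau_m = %g ms, ",
                     "dt = %g ms\n"),
              x$n_conductor, x$n_student, x$v_reset, x$v_thresh,
              1e3 * x$tau_m, 1e3 * x$dt))
  invisible(x)
}

#' Per-neuron spike-time container
#'
#' @param times List of numeric vectors, one per neuron, of strictly
#'   increasing spike times in seconds within `[t_start, t_end]`.
#' @param t_start,t_end Time range of the recording.
#' @return An object of class `"spike_train"`.
#' @export
spike_train <- function(times, t_start = 0, t_end = 1) {
  stopifnot(is.list(times))
  for (v in times) {
    if (length(v) > 1 && any(diff(v) <= 0)) {
      stop("spike times must be strictly increasing per neuron",
           call. = FALSE)
    }
    if (length(v) && (min(v) < t_start - 1e-9 || max(v) > t_end + 1e-9)) {
      stop("spike times outside [t_start, t_end]", call. = FALSE)
    }
  }
  structure(list(times = times, t_start = t_start, t_end = t_end),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d neuron(s), %d spikes on [%g, %g] s\n",
              length(x$times), sum(lengths(x$times)), x$t_start, x$t_end))
  invisible(x)
}

#' @export
length.spike_train <- function(x) length(x$times)

#' Voltage-dependent NMDA gating factor
#'
#' Magnesium-block gating of the NMDA receptor current,
#' \deqn{G(V) = \left[1 + \frac{[Mg]}{3.57\,mM}\,
#'   e^{-V/16.13\,mV}\right]^{-1},}
#' strictly increasing in `V` for positive magnesium concentration and
#' approaching 1 at depolarized potentials.
#'
#' @param v Membrane potential in mV (vectorized).
#' @param mg Magnesium concentration in mM (default 1).
#' @return Gating fraction in (0, 1].
#' @export
nmda_gating <- function(v, mg = 1) {
  1 / (1 + (mg / 3.57) * exp(-v / 16.13))
}

#' Jittered conductor burst spike trains
#'
#' Each conductor neuron fires one burst at a fixed moment of the program,
#' with spikes spaced at the intra-burst rate (632 Hz by default). Burst
#' onsets tile the program evenly. Spike counts alternate deterministically
#' between the low and high end of `burst_spikes` (5 and 6 by default).
#' When `jitter = TRUE`, each rendition redraws a uniform onset jitter
#' (+/- 0.3 ms) and per-spike jitter (+/- 0.2 ms), modelling the timing
#' uncertainty of HVC bursts in vivo.
#'
#' @param grid A [time_grid()] giving the program duration.
#' @param params A [spiking_params()].
#' @param jitter Draw timing jitter (default `TRUE`).
#' @return A [spike_train()] with `params$n_conductor` neurons.
#' @export
generate_conductor_spikes <- function(grid, params, jitter = TRUE) {
  n <- params$n_conductor
  isi <- 1 / params$burst_rate
  counts <- rep(params$burst_spikes, length.out = n)
  max_len <- (max(counts) - 1) * isi
  T <- grid$t_end - grid$t_start
  onsets <- grid$t_start +
    (seq_len(n) - 1) * (T - max_len - params$jitter_onset -
                          params$jitter_spike) / max(1, n - 1) +
    params$jitter_onset + params$jitter_spike
  times <- vector("list", n)
  for (i in seq_len(n)) {
    on <- onsets[i]
    if (jitter) on <- on + runif(1, -params$jitter_onset, params$jitter_onset)
    tk <- on + (seq_len(counts[i]) - 1) * isi
    if (jitter) {
      tk <- tk + runif(counts[i], -params$jitter_spike, params$jitter_spike)
    }
    times[[i]] <- sort(pmin(pmax(tk, grid$t_start), grid$t_end))
  }
  spike_train(times, grid$t_start, grid$t_end)
}

#' Inhomogeneous Poisson tutor spike trains
#'
#' Realizes, per channel of the rate program `f`, an inhomogeneous Poisson
#' process by per-bin thinning: spike counts in each grid bin are Poisson
#' with mean `f * dt` and are placed uniformly within the bin.
#'
#' @param f Non-negative rate [signal()] in Hz (rows = tutor neurons).
#' @return A [spike_train()] with one neuron per row of `f`.
#' @export
generate_poisson_tutor <- function(f) {
  if (any(f$values < 0)) stop("tutor rates must be non-negative",
                              call. = FALSE)
  grid <- f$grid
  times <- vector("list", nrow(f$values))
  for (j in seq_len(nrow(f$values))) {
    # bin k spans [t_k, t_k + dt); last sample dropped as a degenerate bin
    lam <- f$values[j, -grid$n] * grid$dt
    counts <- rpois(length(lam), lam)
    idx <- rep(seq_along(lam), counts)
    tk <- grid$times[idx] + runif(length(idx)) * grid$dt
    times[[j]] <- sort(tk)
  }
  spike_train(times, grid$t_start, grid$t_end)
}

#' Firing-rate estimate from spike trains
#'
#' Causal exponential-kernel estimate,
#' \deqn{r(t) = \frac{1}{\tau_{est}} \sum_k e^{-(t-t_k)/\tau_{est}}
#'   \quad (t \ge t_k),}
#' evaluated exactly on the grid (spikes between samples are decayed to the
#' next sample). This estimator feeds the plasticity rule and the burst
#' detector; timescales of 5-40 ms are typical.
#'
#' @param spikes A [spike_train()].
#' @param tau_est Kernel timescale in seconds.
#' @param grid A [time_grid()] to evaluate on.
#' @return A [signal()] in Hz, one row per neuron.
#' @export
estimate_rates <- function(spikes, tau_est, grid) {
  stopifnot(tau_est > 0)
  vals <- matrix(0, length(spikes$times), grid$n)
  for (j in seq_along(spikes$times)) {
    vals[j, ] <- .rate_from_spikes(spikes$times[[j]], grid$times, tau_est)
  }
  signal(vals, grid, units = "Hz")
}

#' Initial conductor-student weight matrix
#'
#' Each student neuron receives exactly `synapses_per_student` conductor
#' synapses chosen uniformly at random; nonzero weights are log-normal with
#' the moment-matched mean `w_mean` and s.d. `w_sd` (in pA). Absent synapses
#' are zeros and stay prunable during learning.
#'
#' @param params A [spiking_params()].
#' @return `n_conductor x n_student` weight matrix (pA).
#' @export
init_spiking_weights <- function(params) {
  nc <- params$n_conductor; ns <- params$n_student
  k <- params$synapses_per_student
  if (k > nc) stop("more synapses per student than conductor neurons",
                   call. = FALSE)
  sdlog2 <- log(1 + (params$w_sd / params$w_mean)^2)
  meanlog <- log(params$w_mean) - sdlog2 / 2
  W <- matrix(0, nc, ns)
  for (j in seq_len(ns)) {
    idx <- sample.int(nc, k)
    W[idx, j] <- stats::rlnorm(k, meanlog, sqrt(sdlog2))
  }
  W
}

#' Simulate the spiking student network for one rendition
#'
#' Steps the leaky integrate-and-fire network (exponential-Euler updates,
#' exact for inputs held constant within a step) under conductor and tutor
#' spike input. Within each step, input spikes are applied first, then the
#' membrane is updated, then thresholds are tested; this ordering is fixed so
#' runs are exactly reproducible.
#'
#' @param cond_spikes Conductor [spike_train()]
#'   ([generate_conductor_spikes()]).
#' @param tut_spikes Tutor [spike_train()] with one neuron per student
#'   ([generate_poisson_tutor()]), or `NULL` for a silent tutor.
#' @param W Conductor-student weight matrix (pA).
#' @param params A [spiking_params()].
#' @param t_end Simulation end time in seconds (default 1).
#' @param i_ext Constant injected current per student neuron, pA (scalar or
#'   vector; default 0). Used mainly for calibration against closed-form LIF
#'   responses.
#' @param record_v Record the membrane potential at every step (default
#'   `FALSE`).
#' @return A list with `spikes` (a [spike_train()] of student spikes) and,
#'   if requested, `v` (matrix `n_student x n_steps` in mV).
#' @export
simulate_lif <- function(cond_spikes, tut_spikes, W, params, t_end = 1,
                         i_ext = 0, record_v = FALSE) {
  ns <- ncol(W)
  if (!is.null(tut_spikes) && length(tut_spikes) != ns) {
    stop("tutor spike train must have one neuron per student", call. = FALSE)
  }
  flat <- flatten_spikes(cond_spikes)
  tfl <- if (is.null(tut_spikes)) {
    list(t = numeric(0), id = integer(0))
  } else {
    flatten_spikes(tut_spikes)
  }
  n_steps <- as.integer(round(t_end / params$dt))
  i_ext <- rep_len(as.numeric(i_ext), ns)
  res <- .lif_simulate(n_steps, params$dt, flat$t, flat$id - 1L,
                       tfl$t, tfl$id - 1L, W, unclass(params), i_ext,
                       record_v)
  times <- split(res$time, factor(res$neuron, levels = seq_len(ns)))
  out <- list(spikes = spike_train(unname(times), 0, t_end))
  if (record_v) out$v <- res$v
  out
}

flatten_spikes <- function(spikes) {
  t <- unlist(spikes$times, use.names = FALSE)
  id <- rep(seq_along(spikes$times), lengths(spikes$times))
  o <- order(t)
  list(t = t[o], id = id[o])
}
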