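#' Hysteresis burst detection on a firing-rate trace
#'
#' A burst starts when the estimated firing rate rises above the on-threshold
#' (80 Hz by default) and lasts until the rate falls below the off-threshold
#' (40 Hz). Intervals are non-overlapping and sorted; a burst still open at
#' the end of the recording is closed there.
#'
#' @param rate A [signal()] in Hz (one row per neuron).
#' @param on Threshold that opens a burst, Hz (default 80).
#' @param off Threshold that closes a burst, Hz (default 40).
#' @return A data frame with columns `neuron`, `start`, `end` (seconds).
#' @export
detect_bursts <- function(rate, on = 80, off = 40) {
  out <- list()
  tm <- rate$grid$times
  for (j in seq_len(nrow(rate$values))) {
    r <- rate$values[j, ]
    inb <- FALSE
    st <- NA_real_
    starts <- c(); ends <- c()
    for (k in seq_along(r)) {
      if (!inb && r[k] > on) {
        inb <- TRUE
        st <- tm[k]
      } else if (inb && r[k] < off) {
        inb <- FALSE
        starts <- c(starts, st); ends <- c(ends, tm[k])
      }
    }
    if (inb) { starts <- c(starts, st); ends <- c(ends, tm[length(tm)]) }
    if (length(starts)) {
      out[[j]] <- data.frame(neuron = j, start = starts, end = ends)
    }
  }
  if (!length(out)) {
    return(data.frame(neuron = integer(0), start = numeric(0),
                      end = numeric(0)))
  }
  do.call(rbind, out)
}

#' Descriptive spike-train statistics
#'
#' Computes, per neuron and averaged across neurons: mean firing rate
#' (count / duration), coefficient of variation and skewness of the
#' inter-spike-interval distribution, and burst statistics (frequency, mean
#' duration, and firing rate within bursts) obtained by applying
#' [detect_bursts()] to the exponential-kernel rate estimate. Neurons with
#' too few spikes for an ISI statistic (fewer than 2 ISIs for the CV, 3 for
#' the skewness) contribute `NA` to that entry; fully empty trains yield rate
#' 0 and undefined ISI statistics.
#'
#' @param spikes A [spike_train()].
#' @param rate_kernel_tau Rate-estimation kernel timescale in seconds
#'   (default 20 ms).
#' @param grid Optional [time_grid()] for the rate estimate; defaults to a
#'   1 ms grid over the train's time range.
#' @param burst_on,burst_off Burst detection thresholds in Hz.
#' @param pooled If `TRUE`, ISI statistics pool all neurons' intervals
#'   instead of the default average of per-neuron statistics.
#' @return An object of class `"spike_stats"`: a list with entries
#'   `mean_rate`, `isi_cv`, `isi_skewness`, `burst_frequency`,
#'   `mean_burst_duration`, `intra_burst_rate`, plus a `per_neuron` data
#'   frame.
#' @export
spike_statistics <- function(spikes, rate_kernel_tau = 0.02, grid = NULL,
                             burst_on = 80, burst_off = 40, pooled = FALSE) {
  dur <- spikes$t_end - spikes$t_start
  if (is.null(grid)) grid <- time_grid(spikes$t_start, spikes$t_end, 1e-3)
  n <- length(spikes$times)
  rate_est <- estimate_rates(spikes, rate_kernel_tau, grid)
  bursts <- detect_bursts(rate_est, on = burst_on, off = burst_off)

  per <- data.frame(neuron = seq_len(n), mean_rate = NA_real_,
                    isi_cv = NA_real_, isi_skewness = NA_real_,
                    burst_frequency = NA_real_,
                    mean_burst_duration = NA_real_,
                    intra_burst_rate = NA_real_)
  all_isi <- list()
  for (j in seq_len(n)) {
    tk <- spikes$times[[j]]
    per$mean_rate[j] <- length(tk) / dur
    isi <- diff(tk)
    all_isi[[j]] <- isi
    if (length(isi) >= 2) per$isi_cv[j] <- sd_pop(isi) / mean(isi)
    if (length(isi) >= 3) per$isi_skewness[j] <- skewness(isi)
    bj <- bursts[bursts$neuron == j, , drop = FALSE]
    per$burst_frequency[j] <- nrow(bj) / dur
    if (nrow(bj)) {
      bdur <- bj$end - bj$start
      per$mean_burst_duration[j] <- mean(bdur)
      nspk <- vapply(seq_len(nrow(bj)), function(b) {
        sum(tk >= bj$start[b] & tk <= bj$end[b])
      }, numeric(1))
      per$intra_burst_rate[j] <- sum(nspk) / sum(bdur)
    }
  }

  if (pooled) {
    isi <- unlist(all_isi)
    cv <- if (length(isi) >= 2) sd_pop(isi) / mean(isi) else NA_real_
    sk <- if (length(isi) >= 3) skewness(isi) else NA_real_
  } else {
    cv <- mean(per$isi_cv, na.rm = TRUE)
    sk <- mean(per$isi_skewness, na.rm = TRUE)
  }
  res <- list(mean_rate = mean(per$mean_rate),
              isi_cv = if (is.nan(cv)) NA_real_ else cv,
              isi_skewness = if (is.nan(sk)) NA_real_ else sk,
              burst_frequency = mean(per$burst_frequency, na.rm = TRUE),
              mean_burst_duration =
                mean_or_na(per$mean_burst_duration),
              intra_burst_rate = mean_or_na(per$intra_burst_rate),
              per_neuron = per)
  class(res) <- "spike_stats"
  res
}

mean_or_na <- function(x) {
  if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
}

# population (1/n) standard deviation: the ISI CV convention, so that the
# hand-computable small cases come out exact
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

skewness <- function(x) {
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) return(0)
  mean((x - m)^3) / s^3
}

#' @export
print.spike_stats <- function(x, ...) {
  cat(sprintf(paste0("<spike_stats> rate = %.2f Hz, ISI CV = %.3f, ",
                     "ISI skew = %.3f, bursts = %.2f /s (%.1f ms, %.1f Hz)\n"),
              x$mean_rate, x$isi_cv, x$isi_skewness, x$burst_frequency,
              1e3 * x$mean_burst_duration, x$intra_burst_rate))
  invisible(x)
}

#' Relative error between simulated and observed statistics
#'
#' Scale-free objective comparing a vector of simulated statistics against
#' observed ones:
#' \deqn{\left[\sum_i (x_i^{sim}/x_i^{obs} - 1)^2\right]^{1/2}.}
#' Undefined entries (`NA` in either vector) are excluded with a warning, as
#' happens when a train has too few ISIs for a statistic.
#'
#' @param sim,obs Numeric vectors (or `spike_stats` objects) of equal length;
#'   `obs` entries must be nonzero.
#' @return Scalar relative error (0 iff the vectors coincide).
#' @export
relative_error <- function(sim, obs) {
  sim <- stats_vector(sim); obs <- stats_vector(obs)
  if (length(sim) != length(obs)) {
    stop("`sim` and `obs` must have equal length", call. = FALSE)
  }
  keep <- !(is.na(sim) | is.na(obs))
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " undefined statistic(s) from the ",
            "relative error")
    sim <- sim[keep]; obs <- obs[keep]
  }
  if (any(obs == 0)) stop("observed statistics must be nonzero",
                          call. = FALSE)
  sqrt(sum((sim / obs - 1)^2))
}

stats_vector <- function(x) {
  if (inherits(x, "spike_stats")) {
    unlist(x[c("mean_rate", "isi_cv", "isi_skewness", "burst_frequency",
               "mean_burst_duration", "intra_burst_rate")])
  } else {
    as.numeric(x)
  }
}

#' Count pruned synapses
#'
#' A synapse is considered pruned when the current it admits after a
#' pre-synaptic spike falls below a threshold (1 pA by default). Only entries
#' of the ever-connected mask are counted, so synapses absent from the start
#' are not reported as pruned.
#'
#' @param W Weight matrix in pA.
#' @param threshold Pruning threshold in pA (default 1).
#' @param connected Logical mask of ever-connected synapses; defaults to
#'   `W > 0` (call with the initial weights' mask to track pruning during
#'   learning).
#' @return Number of pruned synapses.
#' @seealso [mean_inputs_per_student()] for the surviving-input count.
#' @export
count_pruned <- function(W, threshold = 1, connected = NULL) {
  if (is.null(connected)) connected <- W > 0
  sum(connected & W < threshold)
}

#' Mean surviving conductor inputs per student neuron
#'
#' Companion of [count_pruned()]: the average number of conductor synapses
#' per student neuron whose weight is at or above the pruning threshold.
#'
#' @inheritParams count_pruned
#' @return Mean count of surviving inputs per student neuron.
#' @export
mean_inputs_per_student <- function(W, threshold = 1) {
  mean(colSums(W >= threshold))
}
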