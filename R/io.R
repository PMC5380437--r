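#' Write a signal as CSV
#'
#' Plain-text persistence: a `time` column followed by one column per
#' channel. The unit label is stored in a `# units:` comment on the first
#' line.
#'
#' @param x A [signal()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(x, path) {
  df <- data.frame(time = x$grid$times, t(x$values))
  names(df) <- c("time", paste0("ch", seq_len(nrow(x$values))))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# units: %s", x$units), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a signal written by [write_signal_csv()]
#'
#' @param path CSV file path.
#' @return A [signal()].
#' @export
read_signal_csv <- function(path) {
  first <- readLines(path, n = 1)
  units <- sub("^# units: ?", "", first)
  df <- read.csv(path, comment.char = "#")
  tm <- df$time
  grid <- time_grid(tm[1], tm[length(tm)], tm[2] - tm[1])
  signal(t(as.matrix(df[, -1, drop = FALSE])), grid, units = units)
}

#' Write spike trains as two-column CSV
#'
#' Columns `neuron` (1-based id) and `time_s`; empty neurons are preserved
#' through the `# neurons:` header line.
#'
#' @param spikes A [spike_train()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spikes_csv <- function(spikes, path) {
  flat <- flatten_spikes(spikes)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# neurons: %d range: %g %g", length(spikes$times),
                     spikes$t_start, spikes$t_end), con)
  write.csv(data.frame(neuron = flat$id, time_s = flat$t), con,
            row.names = FALSE)
  invisible(path)
}

#' Read spike trains written by [write_spikes_csv()]
#'
#' @param path CSV file path.
#' @return A [spike_train()].
#' @export
read_spikes_csv <- function(path) {
  hdr <- strsplit(readLines(path, n = 1), " +")[[1]]
  n <- as.integer(hdr[3]); t0 <- as.numeric(hdr[5]); t1 <- as.numeric(hdr[6])
  df <- read.csv(path, comment.char = "#")
  times <- lapply(seq_len(n), function(j) sort(df$time_s[df$neuron == j]))
  spike_train(times, t0, t1)
}

#' Write burst intervals as BED-like text
#'
#' Three tab-separated columns without header: neuron id, start (s), end (s).
#'
#' @param bursts Data frame from [detect_bursts()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bursts_bed <- function(bursts, path) {
  utils::write.table(bursts, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Persist a run configuration as YAML
#'
#' @param config A [rate_config()] or [spiking_config()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(strip_classes(config), path)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' Rebuilds the classed parameter objects from the plain YAML key-value
#' structure written by [write_config()].
#'
#' @param path YAML file path.
#' @return A `"run_config"`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$plasticity <- do.call(plasticity_params,
                            c(raw$plasticity,
                              list(enforce_normalization = FALSE)))
  raw$tutor <- do.call(tutor_spec, raw$tutor)
  if (!is.null(raw$target)) {
    raw$target$amplitude <- as.numeric(raw$target$amplitude)
    raw$target <- do.call(target_spec, raw$target)
  }
  if (!is.null(raw$spiking)) {
    raw$spiking$burst_spikes <- as.numeric(raw$spiking$burst_spikes)
    raw$spiking <- do.call(spiking_params, raw$spiking)
  }
  if (identical(raw$engine, "rate")) {
    keep <- setdiff(names(raw), "engine")
    do.call(rate_config, raw[intersect(keep, names(formals(rate_config)))])
  } else {
    keep <- setdiff(names(raw), c("engine", "dt"))
    cfg <- do.call(spiking_config,
                   raw[intersect(keep, names(formals(spiking_config)))])
    cfg
  }
}

strip_classes <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_classes)
    attributes(x) <- list(names = names(x))
  }
  x
}
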