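#' Spike train objects
#'
#' A spike train is the package's universal I/O currency: an ordered list of
#' (time, channel) events. It is stored as a data.frame with numeric column
#' `time` (ms) and integer column `channel` (1-based), plus attributes
#' `n_channels` and `duration` (ms).
#'
#' @param time Numeric vector of spike times in ms (>= 0).
#' @param channel Integer vector of channel indices in `1..n_channels`.
#' @param n_channels Total number of channels.
#' @param duration Duration of the recording in ms; defaults to the last
#'   spike time (0 for an empty train).
#' @return An object of classes `spike_train` and `data.frame`.
#' @examples
#' st <- spike_train(c(1.5, 3.2, 10), c(1L, 2L, 1L), n_channels = 4)
#' n_spikes(st)
#' @export
spike_train <- function(time = numeric(), channel = integer(),
                        n_channels, duration = NULL) {
  stopifnot(length(time) == length(channel), n_channels >= 1)
  if (length(time)) {
    stopifnot(all(is.finite(time)), all(time >= 0))
    channel <- as.integer(channel)
    if (any(channel < 1L) || any(channel > n_channels)) {
      stop("channel indices must lie in 1..n_channels")
    }
    o <- order(time)
    time <- time[o]; channel <- channel[o]
  }
  if (is.null(duration)) duration <- if (length(time)) max(time) else 0
  stopifnot(duration >= 0)
  structure(
    data.frame(time = as.numeric(time), channel = as.integer(channel)),
    n_channels = as.integer(n_channels),
    duration = as.numeric(duration),
    class = c("spike_train", "data.frame")
  )
}

#' @rdname spike_train
#' @param x A `spike_train`.
#' @export
n_channels <- function(x) attr(x, "n_channels")

#' @rdname spike_train
#' @export
n_spikes <- function(x) nrow(x)

#' @rdname spike_train
#' @export
train_duration <- function(x) attr(x, "duration")

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes on %d channels over %.1f ms\n",
              nrow(x), n_channels(x), train_duration(x)))
  if (nrow(x)) {
    cat(sprintf("  mean rate %.2f Hz/channel\n",
                1000 * nrow(x) / n_channels(x) / max(train_duration(x), 1e-9)))
  }
  invisible(x)
}

#' Read / write spike trains as two-column CSV
#'
#' The on-disk format is a CSV with header `time_ms,channel`. Channel count
#' and duration are restored from the `n_channels` / `duration` arguments
#' (or inferred from the data when omitted).
#'
#' @param train A [spike_train()].
#' @param path File path.
#' @param n_channels,duration Metadata for the restored train; inferred from
#'   the events if `NULL`.
#' @return `read_spike_train_csv` returns a [spike_train()];
#'   `write_spike_train_csv` returns `path` invisibly.
#' @export
write_spike_train_csv <- function(train, path) {
  df <- data.frame(time_ms = train$time, channel = train$channel)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spike_train_csv
#' @export
read_spike_train_csv <- function(path, n_channels = NULL, duration = NULL) {
  df <- utils::read.csv(path)
  stopifnot(all(c("time_ms", "channel") %in% names(df)))
  if (is.null(n_channels)) {
    n_channels <- if (nrow(df)) max(df$channel) else 1L
  }
  spike_train(df$time_ms, df$channel, n_channels = n_channels,
              duration = duration)
}

#' Concatenate spike trains in time
#'
#' Shifts each train by the cumulative duration of its predecessors and
#' merges the events. All trains must share the channel count.
#'
#' @param ... `spike_train` objects.
#' @return A single [spike_train()].
#' @export
concat_trains <- function(...) {
  trains <- list(...)
  stopifnot(length(trains) >= 1L)
  nch <- n_channels(trains[[1L]])
  stopifnot(all(vapply(trains, n_channels, integer(1)) == nch))
  offset <- 0
  times <- list(); chans <- list()
  for (tr in trains) {
    times[[length(times) + 1L]] <- tr$time + offset
    chans[[length(chans) + 1L]] <- tr$channel
    offset <- offset + train_duration(tr)
  }
  spike_train(unlist(times), unlist(chans), n_channels = nch,
              duration = offset)
}

#' Homogeneous Poisson spike train
#'
#' Independent Poisson processes at a common rate on a set of channels;
#' used by the synthetic-data generators.
#'
#' @param rate_hz Firing rate per channel in Hz.
#' @param duration Duration in ms.
#' @param n_channels Number of channels.
#' @param channels Channels that fire (default: all).
#' @return A [spike_train()].
#' @export
poisson_train <- function(rate_hz, duration, n_channels,
                          channels = seq_len(n_channels)) {
  stopifnot(rate_hz >= 0, duration >= 0)
  if (rate_hz == 0 || duration == 0 || length(channels) == 0L) {
    return(spike_train(n_channels = n_channels, duration = duration))
  }
  counts <- stats::rpois(length(channels), rate_hz * duration / 1000)
  ch <- rep(channels, counts)
  tt <- stats::runif(sum(counts), 0, duration)
  spike_train(tt, ch, n_channels = n_channels, duration = duration)
}
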