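#' Encode a sequence of evidence vectors as a population-coded spike train
#'
#' For each pattern, the active channel of every observed group fires as a
#' Poisson process at `active_rate_hz` for `pattern_ms`; all other channels
#' are silent. A `gap_ms` period of global silence separates consecutive
#' patterns (avoiding EPSP overlap between patterns). Missing groups
#' (`NA` in the evidence vector) stay silent for the whole pattern.
#'
#' With `osc_amplitude > 0` the instantaneous rate is modulated as
#' `active_rate_hz * (1 + A * sin(2 pi f t / 1000 + phase))`, shared across
#' all channels, by thinning a Poisson process at rate
#' `active_rate_hz * (1 + A)`. The modulation preserves the average rate
#' over whole periods. `A > 1` is rejected (negative rates).
#'
#' @param patterns Integer matrix (`n_patterns` x `n_groups`, `NA` =
#'   missing) or a list of evidence vectors.
#' @param code A [population_code()].
#' @param active_rate_hz Firing rate of active channels in Hz.
#' @param pattern_ms Presentation duration per pattern in ms.
#' @param gap_ms Silent gap between patterns in ms.
#' @param osc_amplitude,osc_freq_hz,osc_phase Optional sinusoidal rate
#'   modulation (relative amplitude in `[0, 1]`, frequency in Hz, phase in
#'   radians). The oscillation phase is continuous across the whole stream.
#' @return A [spike_train()] with attribute `pattern_onsets` (ms) giving
#'   the onset of each pattern.
#' @export
encode_stream <- function(patterns, code, active_rate_hz = 25,
                          pattern_ms = 40, gap_ms = 10,
                          osc_amplitude = 0, osc_freq_hz = 20,
                          osc_phase = 0) {
  if (is.list(patterns)) patterns <- do.call(rbind, patterns)
  patterns <- matrix(as.integer(patterns), ncol = code$n_groups)
  stopifnot(active_rate_hz >= 0, pattern_ms > 0, gap_ms >= 0)
  if (osc_amplitude > 1) stop("oscillation amplitude > 1 gives negative rates")
  np <- nrow(patterns)
  cycle <- pattern_ms + gap_ms
  onsets <- (seq_len(np) - 1L) * cycle
  if (active_rate_hz == 0 || np == 0L) {
    out <- spike_train(n_channels = code$n_channels, duration = np * cycle)
    attr(out, "pattern_onsets") <- onsets
    return(out)
  }
  # active channel per (pattern, observed group)
  grp <- rep(seq_len(code$n_groups), each = np)
  val <- as.vector(patterns)
  keep <- !is.na(val)
  pat_idx <- rep(seq_len(np), times = code$n_groups)[keep]
  chan <- channel_for(code, grp[keep], val[keep])
  # Poisson counts at the (possibly thinning-inflated) rate
  top_rate <- active_rate_hz * (1 + osc_amplitude)
  counts <- stats::rpois(length(chan), top_rate * pattern_ms / 1000)
  tot <- sum(counts)
  if (tot == 0L) {
    out <- spike_train(n_channels = code$n_channels, duration = np * cycle)
    attr(out, "pattern_onsets") <- onsets
    return(out)
  }
  ch <- rep(chan, counts)
  t_local <- stats::runif(tot, 0, pattern_ms)
  t_abs <- onsets[rep(pat_idx, counts)] + t_local
  if (osc_amplitude > 0) {
    accept <- stats::runif(tot) <
      (1 + osc_amplitude * sin(2 * pi * osc_freq_hz * t_abs / 1000 + osc_phase)) /
      (1 + osc_amplitude)
    ch <- ch[accept]; t_abs <- t_abs[accept]
  }
  out <- spike_train(t_abs, ch, n_channels = code$n_channels,
                     duration = np * cycle)
  attr(out, "pattern_onsets") <- onsets
  out
}

#' Decode the instantaneous evidence from a spike train
#'
#' For each group, returns the value whose channel spiked within
#' `(t - sigma, t]`; `NA` (missing) if no channel of the group spiked. If
#' several channels of one group spiked in-window, the most recent spike
#' wins (the theory excludes this case; the decoder is diagnostic only).
#'
#' @param train A [spike_train()].
#' @param t Evaluation time in ms.
#' @param code A [population_code()].
#' @param sigma Window length in ms.
#' @return Integer evidence vector (length `n_groups`, `NA` = missing).
#' @export
decode_evidence <- function(train, t, code, sigma) {
  stopifnot(sigma > 0)
  sel <- train$time > t - sigma & train$time <= t
  ev <- rep(NA_integer_, code$n_groups)
  if (!any(sel)) return(ev)
  tt <- train$time[sel]; ch <- train$channel[sel]
  o <- order(tt)  # later spikes overwrite earlier ones
  for (i in o) {
    g <- code$group_of[ch[i]]
    ev[g] <- code$value_of[ch[i]]
  }
  ev
}

#' Empirical missing-value rate of an encoded stream
#'
#' Fraction of groups with no spike in the integration window `(t - sigma, t]`
#' at sampled times `t`, i.e. groups an output neuron would read as missing.
#' When every group has the same missing probability, a converged weight
#' matrix is offset by the constant `log(1 - rate)`; this estimate is used
#' to correct per-group weight normalization sums.
#'
#' @param train A [spike_train()].
#' @param code A [population_code()].
#' @param sigma Integration window in ms.
#' @param times Sample times in ms; default 400 points spread over the
#'   stream (skipping the initial `sigma` ms).
#' @return Scalar in `[0, 1]`.
#' @export
estimate_missing_rate <- function(train, code, sigma, times = NULL) {
  if (is.null(times)) {
    dur <- train_duration(train)
    times <- seq(sigma, dur, length.out = 400L)
  }
  miss <- 0L
  for (t in times) {
    ev <- decode_evidence(train, t, code, sigma)
    miss <- miss + sum(is.na(ev))
  }
  miss / (length(times) * code$n_groups)
}

#' Expected in-window group occupancy of a stream
#'
#' Mean number of channels per group with at least one spike in the
#' integration window `(t - sigma, t]`, averaged over sampled times. At
#' the plasticity equilibrium the per-group sums of `exp(w - log c)`
#' converge to exactly this quantity: it generalizes the `1 - missing`
#' correction to streams where a window can straddle two consecutive
#' patterns and catch both of a group's channels.
#'
#' @inheritParams estimate_missing_rate
#' @param per_group Return one occupancy per group instead of the mean.
#' @return Mean active channels per group per window (scalar, or a
#'   vector over groups when `per_group = TRUE`).
#' @export
estimate_group_occupancy <- function(train, code, sigma, times = NULL,
                                     per_group = FALSE) {
  if (is.null(times)) {
    dur <- train_duration(train)
    times <- seq(sigma, dur, length.out = 400L)
  }
  cnt <- numeric(code$n_groups)
  for (t in times) {
    sel <- train$time > t - sigma & train$time <= t
    ch <- unique(train$channel[sel])
    g <- tabulate(code$group_of[ch], nbins = code$n_groups)
    cnt <- cnt + g
  }
  cnt <- cnt / length(times)
  if (per_group) cnt else mean(cnt)
}

#' Group occupancy at a neuron's own spike times
#'
#' For each output neuron, the fraction of its spikes at which each input
#' group had at least one spike in the preceding window — the empirical
#' estimate of `P(group observed | neuron fires)`. This is the offset the
#' synaptic equilibrium carries: converged weights satisfy
#' `w = log P(channel active in window | neuron fires) + log c`, so
#' per-group sums of `exp(w - log c)` equal exactly this conditional
#' occupancy.
#'
#' @param input The input [spike_train()].
#' @param output The circuit's output [spike_train()] (channels =
#'   neurons).
#' @param code A [population_code()].
#' @param sigma Integration window in ms.
#' @param K Number of output neurons.
#' @param max_per_neuron Cap on sampled spikes per neuron.
#' @param floor Lower bound applied to the estimates (guards division).
#' @return `K x n_groups` matrix of conditional occupancies.
#' @export
occupancy_at_spikes <- function(input, output, code, sigma, K,
                                max_per_neuron = 8000L, floor = 0.05) {
  cnt <- matrix(0, K, code$n_groups)
  nk <- numeric(K)
  sel_sp <- unlist(lapply(seq_len(K), function(k) {
    sk <- which(output$channel == k)
    if (length(sk) > max_per_neuron) {
      sk[round(seq(1, length(sk), length.out = max_per_neuron))]
    } else sk
  }))
  for (ii in sel_sp) {
    t <- output$time[ii]
    k <- output$channel[ii]
    lo <- findInterval(t - sigma, input$time) + 1L
    hi <- findInterval(t, input$time)
    if (hi >= lo) {
      g <- tabulate(code$group_of[unique(input$channel[lo:hi])],
                    nbins = code$n_groups)
      cnt[k, ] <- cnt[k, ] + g
    }
    nk[k] <- nk[k] + 1
  }
  pmax(cnt / pmax(nk, 1), floor)
}
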