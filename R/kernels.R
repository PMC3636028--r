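#' EPSP kernel specification
#'
#' Describes how a presynaptic spike is turned into a postsynaptic activation
#' trace `ytilde_i(t)`. Two kernel families are supported:
#'
#' * `"rectangular_renewable"`: the trace is 1 for `sigma` ms after a spike
#'   and 0 otherwise. Further spikes within the window do not add; they only
#'   extend the window (a renewable step function), so the trace is binary.
#' * `"alpha"`: each spike contributes an alpha-shaped EPSP
#'   `eps(s) = A * (exp(-s / tau_decay) - exp(-s / tau_rise))` for `s > 0`,
#'   contributions from different spikes add. `A` is chosen so that the peak
#'   of a single EPSP equals `peak_amplitude` (default 1, so that one isolated
#'   spike contributes its synaptic weight exactly once).
#'
#' @param kind `"rectangular_renewable"` or `"alpha"`.
#' @param sigma Window length in ms for the rectangular kernel.
#' @param tau_rise,tau_decay Rise and decay time constants in ms for the
#'   alpha kernel. Must satisfy `0 < tau_rise < tau_decay`.
#' @param peak_amplitude Peak value of a single alpha-kernel EPSP (unitless).
#' @return An object of class `kernel_spec`.
#' @examples
#' kernel_spec("alpha", tau_rise = 1, tau_decay = 15)
#' kernel_spec("rectangular_renewable", sigma = 40)
#' @export
kernel_spec <- function(kind = c("alpha", "rectangular_renewable"),
                        sigma = 40, tau_rise = 1, tau_decay = 15,
                        peak_amplitude = 1) {
  kind <- match.arg(kind)
  stopifnot(sigma > 0, tau_rise > 0, tau_decay > tau_rise, peak_amplitude > 0)
  structure(
    list(kind = kind, sigma = sigma, tau_rise = tau_rise,
         tau_decay = tau_decay, peak_amplitude = peak_amplitude),
    class = "kernel_spec"
  )
}

#' @export
print.kernel_spec <- function(x, ...) {
  if (x$kind == "rectangular_renewable") {
    cat(sprintf("<kernel_spec> rectangular_renewable, sigma = %g ms\n", x$sigma))
  } else {
    cat(sprintf("<kernel_spec> alpha, tau_rise = %g ms, tau_decay = %g ms, peak = %g\n",
                x$tau_rise, x$tau_decay, x$peak_amplitude))
  }
  invisible(x)
}

#' Time of the peak of a single alpha-kernel EPSP
#'
#' Closed-form argmax of `exp(-s/tau_decay) - exp(-s/tau_rise)`:
#' `s* = tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)`.
#'
#' @param kernel A [kernel_spec()] of kind `"alpha"`.
#' @return Peak time in ms.
#' @export
alpha_peak_time <- function(kernel) {
  stopifnot(kernel$kind == "alpha")
  tr <- kernel$tau_rise; td <- kernel$tau_decay
  tr * td / (td - tr) * log(td / tr)
}

#' Normalization constant of the alpha kernel
#'
#' The multiplier `A` such that `A * (exp(-s/tau_decay) - exp(-s/tau_rise))`
#' attains `peak_amplitude` at its maximum.
#'
#' @inheritParams alpha_peak_time
#' @return Amplitude multiplier (unitless).
#' @export
alpha_amplitude <- function(kernel) {
  s <- alpha_peak_time(kernel)
  kernel$peak_amplitude /
    (exp(-s / kernel$tau_decay) - exp(-s / kernel$tau_rise))
}

#' Evaluate a single alpha-kernel EPSP
#'
#' @inheritParams alpha_peak_time
#' @param s Time since the presynaptic spike, in ms (vectorized).
#' @return `eps(s)`, zero for `s <= 0`.
#' @export
alpha_epsp <- function(s, kernel) {
  A <- alpha_amplitude(kernel)
  ifelse(s > 0, A * (exp(-s / kernel$tau_decay) - exp(-s / kernel$tau_rise)), 0)
}

#' Rectangular renewable EPSP trace of one channel
#'
#' Returns 1 iff at least one spike of the channel falls in the window
#' `(t - sigma, t]`. Multiple spikes in the window extend it; they never add.
#'
#' @param spike_times Sorted numeric vector of spike times (ms).
#' @param t Evaluation time(s) in ms (vectorized).
#' @param sigma Window length in ms.
#' @return 0/1 vector, one entry per element of `t`.
#' @export
rectangular_trace <- function(spike_times, t, sigma) {
  stopifnot(sigma > 0)
  if (length(spike_times) == 0L) return(numeric(length(t)))
  vapply(t, function(tt) {
    as.numeric(any(spike_times > tt - sigma & spike_times <= tt))
  }, numeric(1))
}

#' Alpha-kernel EPSP trace of one channel
#'
#' Direct convolution `ytilde(t) = sum_f eps(t - t_f)` over the spike list.
#' The simulation loop computes the same quantity incrementally through two
#' exponential state variables per channel; see [run_simulation()].
#'
#' @param spike_times Sorted numeric vector of spike times (ms).
#' @param t Evaluation time(s) in ms (vectorized).
#' @param kernel A [kernel_spec()] of kind `"alpha"`.
#' @return Nonnegative trace values, one per element of `t`.
#' @export
alpha_trace <- function(spike_times, t, kernel) {
  stopifnot(kernel$kind == "alpha")
  if (length(spike_times) == 0L) return(numeric(length(t)))
  vapply(t, function(tt) sum(alpha_epsp(tt - spike_times, kernel)), numeric(1))
}

#' Evaluate traces for all channels of a spike train
#'
#' Convenience wrapper computing `ytilde_i(t)` for every channel `i` at a
#' single time point, under either kernel family.
#'
#' @param train A [spike_train()].
#' @param t Evaluation time in ms (scalar).
#' @param kernel A [kernel_spec()].
#' @return Numeric vector of length `n_channels(train)`.
#' @export
trace_at <- function(train, t, kernel) {
  n <- n_channels(train)
  y <- numeric(n)
  sp <- split(train$time, factor(train$channel, levels = seq_len(n)))
  for (i in seq_len(n)) {
    ts <- sp[[i]]
    if (length(ts) == 0L) next
    y[i] <- if (kernel$kind == "alpha") {
      alpha_trace(ts, t, kernel)
    } else {
      rectangular_trace(ts, t, kernel$sigma)
    }
  }
  y
}

#' Incremental trace evaluation at step boundaries
#'
#' Computes `ytilde_i(s * dt)` for all channels and steps with the same
#' state-variable recursion the simulation loop uses (two exponential
#' states per channel for the alpha kernel, a last-spike register for the
#' rectangular kernel). Exact — not approximate — at step boundaries:
#' spike contributions enter with their true spike times.
#'
#' @param train A [spike_train()].
#' @param kernel A [kernel_spec()].
#' @param dt Step in ms.
#' @param n_steps Number of steps; defaults to cover the train duration.
#' @return `n_steps x n_channels` matrix of trace values at times
#'   `dt, 2 dt, ..., n_steps dt`.
#' @export
trace_series <- function(train, kernel, dt = 1, n_steps = NULL) {
  n <- n_channels(train)
  if (is.null(n_steps)) n_steps <- ceiling(train_duration(train) / dt)
  out <- matrix(0, n_steps, n)
  alpha <- kernel$kind == "alpha"
  if (alpha) {
    A <- alpha_amplitude(kernel)
    dec_d <- exp(-dt / kernel$tau_decay)
    dec_r <- exp(-dt / kernel$tau_rise)
    yd <- numeric(n); yr <- numeric(n)
  } else {
    last <- rep(-Inf, n)
  }
  istep <- floor(train$time / dt) + 1L
  for (s in seq_len(n_steps)) {
    t_end <- s * dt
    sel <- which(istep == s)
    if (alpha) {
      yd <- yd * dec_d; yr <- yr * dec_r
      for (j in sel) {
        ch <- train$channel[j]
        yd[ch] <- yd[ch] + exp(-(t_end - train$time[j]) / kernel$tau_decay)
        yr[ch] <- yr[ch] + exp(-(t_end - train$time[j]) / kernel$tau_rise)
      }
      out[s, ] <- A * (yd - yr)
    } else {
      if (length(sel)) last[train$channel[sel]] <- train$time[sel]
      out[s, ] <- as.numeric(t_end - last < kernel$sigma)
    }
  }
  out
}
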