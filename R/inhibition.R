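#' Inhibition configuration
#'
#' The common inhibitory signal `I(t)` subtracted from every membrane
#' potential is built from up to four components:
#'
#' * a **balancing** term. With `balance = "exact"` the inhibition tracks
#'   the log-sum-exp of the excitatory drives so that the circuit's total
#'   output rate equals `target_output_rate_hz` at every step — the
#'   idealized divisive inhibition under which the total rate `R(t)` is
#'   stochastically independent of the input, as the sampling semantics of
#'   the WTA circuit requires. With `balance = "none"` the raw potentials
#'   drive firing.
#' * a **reset impulse**: after each circuit spike, `A_I * exp(-s / tau_I)`
#'   is added to `I(t)` (`s` = time since the spike), transiently silencing
#'   the circuit (refractory-like suppression).
#' * **Ornstein-Uhlenbeck background noise**, a common stochastic term with
#'   reversion rate `ou_theta` (1/ms), mean `ou_mu` and diffusion
#'   `ou_sigma` (per sqrt(ms)), modelling background synaptic input.
#' * an optional **oscillatory drive** `osc_amplitude *
#'   sin(2 pi osc_freq_hz t / 1000 + osc_phase)` added to all membrane
#'   potentials (i.e. subtracted from `I`).
#'
#' All components are common to the neurons, so none of them changes the
#' winner-identity distribution — only the timing of output spikes.
#'
#' @param balance `"exact"` or `"none"`.
#' @param target_output_rate_hz Total circuit output rate enforced by the
#'   balancing term, in Hz.
#' @param reset_amplitude,reset_tau Reset impulse amplitude `A_I`
#'   (potential units) and decay constant `tau_I` in ms.
#' @param ou_theta,ou_mu,ou_sigma OU process parameters.
#' @param osc_amplitude,osc_freq_hz,osc_phase Oscillatory drive.
#' @return An object of class `inhibition_config`.
#' @export
inhibition_config <- function(balance = c("exact", "none"),
                              target_output_rate_hz = 100,
                              reset_amplitude = 20, reset_tau = 5,
                              ou_theta = 0.05, ou_mu = 0, ou_sigma = 0,
                              osc_amplitude = 0, osc_freq_hz = 20,
                              osc_phase = 0) {
  balance <- match.arg(balance)
  stopifnot(target_output_rate_hz > 0, reset_amplitude >= 0, reset_tau > 0,
            ou_theta > 0, ou_sigma >= 0, osc_amplitude >= 0,
            osc_freq_hz >= 0)
  structure(
    list(balance = balance, target_output_rate_hz = target_output_rate_hz,
         reset_amplitude = reset_amplitude, reset_tau = reset_tau,
         ou_theta = ou_theta, ou_mu = ou_mu, ou_sigma = ou_sigma,
         osc_amplitude = osc_amplitude, osc_freq_hz = osc_freq_hz,
         osc_phase = osc_phase),
    class = "inhibition_config"
  )
}

#' Post-spike reset inhibition
#'
#' Exponentially decaying impulse `A_I * exp(-(t - last_spike) / tau_I)`
#' added to the common inhibition after every circuit spike; 0 if the
#' circuit has not spiked yet.
#'
#' @param t Current time in ms.
#' @param last_spike Time of the last circuit spike in ms, or `NA` if none.
#' @param amplitude Impulse amplitude `A_I`.
#' @param tau Decay time constant `tau_I` in ms.
#' @return Inhibition contribution (scalar).
#' @export
reset_inhibition <- function(t, last_spike, amplitude = 20, tau = 5) {
  if (is.na(last_spike)) return(0)
  stopifnot(t >= last_spike)
  amplitude * exp(-(t - last_spike) / tau)
}

#' One Euler-Maruyama step of an Ornstein-Uhlenbeck process
#'
#' `x <- x + theta * (mu - x) * dt + sigma * sqrt(dt) * N(0, 1)`.
#' The stationary law has variance `sigma^2 / (2 theta)` and lag-`L`
#' autocorrelation `exp(-theta * L)`.
#'
#' @param x Current value.
#' @param dt Step in ms.
#' @param theta Mean-reversion rate (1/ms).
#' @param mu Long-run mean.
#' @param sigma Diffusion coefficient (per sqrt(ms)).
#' @return Updated value.
#' @export
ou_step <- function(x, dt, theta, mu, sigma) {
  stopifnot(dt > 0)
  x + theta * (mu - x) * dt + sigma * sqrt(dt) * stats::rnorm(length(x))
}

#' Sinusoidal oscillation signal
#'
#' `A * sin(2 pi f t / 1000 + phase)` with `t` in ms and `f` in Hz.
#'
#' @param t Time(s) in ms.
#' @param amplitude Amplitude `A`.
#' @param freq_hz Frequency in Hz.
#' @param phase Phase in radians.
#' @return Signal value(s).
#' @export
oscillation_signal <- function(t, amplitude, freq_hz, phase = 0) {
  stopifnot(freq_hz >= 0)
  amplitude * sin(2 * pi * freq_hz * t / 1000 + phase)
}
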