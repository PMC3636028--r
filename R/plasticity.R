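#' Plasticity configuration
#'
#' Selects the learning rule and its constants.
#'
#' Rules (all triggered by circuit spikes, applied only to the firing
#' neuron's weight row):
#'
#' * `"simple"`: at a postsynaptic spike,
#'   `dw = eta * (c * exp(-w) - 1)` if the presynaptic channel was active
#'   (binary trace 1) in the integration window, else `dw = -eta`.
#'   Equilibrium `w* = log P(pre active | post spike) + log(c)`.
#' * `"complex"`: continuous-time generalization,
#'   `dw = eta * (c * ytilde * exp(-w) - 1)` with the (possibly graded)
#'   trace value at the postsynaptic spike time. Reduces to `"simple"` for
#'   binary traces.
#' * `"timing_dependent_ltd"`: LTP as in `"complex"`, but the constant
#'   depression is replaced by a timing-dependent term driven by
#'   presynaptic spikes *after* the postsynaptic spike (time-inversed
#'   kernel). Since that activity is unknown at spike time, the depression
#'   is credited when the later presynaptic spike arrives, via a
#'   postsynaptic spike trace. Equilibrium: log-ratio of presynaptic
#'   firing probability before vs after postsynaptic spikes.
#'
#' The learning rate is either a fixed number or `"variance_tracking"`:
#' a per-synapse adaptive rate estimated from the running first and second
#' moments of the weight, approximating a `1/N` sample-count schedule (see
#' [variance_tracking_rate()]).
#'
#' @param rule `"simple"`, `"complex"` or `"timing_dependent_ltd"`.
#' @param eta Fixed learning rate in `(0, 1)`, or `"variance_tracking"`.
#' @param offset_c Positive offset constant `c = exp(w0)` shifting converged
#'   weights by `log(c)`.
#' @param eta_min,eta_max Clip bounds for the adaptive rate.
#' @param eta_b Fixed learning rate for the intrinsic excitability.
#'   Deliberately slower than the synaptic rate by default: if the priors
#'   harden before the internal models have specialized, the circuit
#'   collapses onto few neurons.
#' @param w_min_rel Floor on `w - log(c)`. Log-probabilities below this are
#'   not resolvable from desk-scale spike counts, and an unbounded
#'   downward drift of a never-active synapse would make the next
#'   potentiation (`eta * c * exp(-w)`) catastrophically stiff.
#' @param delta_max Cap on the magnitude of a single weight or
#'   excitability update (same overshoot guard; equilibria are
#'   unaffected).
#' @param init_spread Initial variance ascribed to the weights by the
#'   adaptive-rate moment tracker; together with the initial weights it
#'   sets the starting learning rate (roughly `init_spread * p / (1 - p)`
#'   at weight `log p`).
#' @param ltd_tau Decay time constant (ms) of the time-inversed LTD window
#'   for `"timing_dependent_ltd"`. Default 30 ms: twice the LTP kernel's
#'   15 ms decay (LTD windows are typically the longer ones).
#' @param ltd_scale Scale factor of the depression term.
#' @return An object of class `plasticity_config`.
#' @export
plasticity_config <- function(rule = c("complex", "simple",
                                       "timing_dependent_ltd"),
                              eta = "variance_tracking", offset_c = 1,
                              eta_min = 1e-4, eta_max = 0.05,
                              eta_b = 0.005,
                              w_min_rel = -7, delta_max = 2,
                              init_spread = 0.25,
                              ltd_tau = 30, ltd_scale = 1) {
  rule <- match.arg(rule)
  adaptive <- identical(eta, "variance_tracking")
  if (!adaptive) stopifnot(is.numeric(eta), eta > 0, eta < 1)
  stopifnot(offset_c > 0, eta_min > 0, eta_min <= eta_max, eta_max < 1,
            is.numeric(eta_b), eta_b > 0, eta_b < 1,
            w_min_rel < 0, delta_max > 0, init_spread > 0,
            ltd_tau > 0, ltd_scale > 0)
  structure(
    list(rule = rule, eta = eta, adaptive = adaptive, offset_c = offset_c,
         eta_min = eta_min, eta_max = eta_max, eta_b = eta_b,
         w_min_rel = w_min_rel, delta_max = delta_max,
         init_spread = init_spread,
         ltd_tau = ltd_tau, ltd_scale = ltd_scale),
    class = "plasticity_config"
  )
}

#' Simple weight-dependent STDP update
#'
#' Triggered by a postsynaptic spike of the neuron owning the synapse:
#' `eta * (c * exp(-w) - 1)` if the presynaptic channel was active in the
#' integration window, `-eta` otherwise. The LTP/LTD amplitude ratio is
#' inversely exponential in the current weight, which places the unique
#' equilibrium of the expected update at
#' `w* = log P(pre active | post spike) + log(c)`.
#'
#' @param w Current weight(s).
#' @param pre_active 0/1 presynaptic activity indicator(s).
#' @param eta Learning rate.
#' @param c Offset constant.
#' @return Weight update(s) `dw`.
#' @export
simple_stdp_delta <- function(w, pre_active, eta, c = 1) {
  pre <- rep_len(pre_active, max(length(w), length(pre_active)))
  ifelse(pre > 0, eta * (c * exp(-w) - 1), -eta)
}

#' Continuous-time (complex) STDP update
#'
#' `eta * (c * ytilde * exp(-w) - 1)` with `ytilde` the EPSP trace value at
#' the postsynaptic spike time. The LTP window follows the EPSP kernel
#' shape; depression is the constant `-eta` offset reached when the trace
#' has decayed to zero. Equilibrium:
#' `w* = log(c * E[ytilde | post spike])`.
#'
#' @param w Current weight(s).
#' @param trace_value Nonnegative EPSP trace(s) at the spike time.
#' @param eta Learning rate.
#' @param c Offset constant.
#' @return Weight update(s) `dw`.
#' @export
complex_stdp_delta <- function(w, trace_value, eta, c = 1) {
  eta * (c * trace_value * exp(-w) - 1)
}

#' Intrinsic excitability update
#'
#' Applied at every circuit spike to every neuron:
#' `eta * (exp(-b) - 1)` for the neuron that fired, `-eta` for the others.
#' Drives `b_k` to `log pi_k`, the log of the neuron's share of circuit
#' spikes, so the normalized exponentials of the excitabilities encode the
#' mixture priors.
#'
#' @param b Current excitability(ies).
#' @param fired Logical: did this neuron emit the circuit spike?
#' @param eta Learning rate.
#' @return Update(s) `db`.
#' @export
intrinsic_delta <- function(b, fired, eta) {
  fired <- rep_len(fired, max(length(b), length(fired)))
  ifelse(fired, eta * (exp(-b) - 1), -eta)
}

#' Net update of the timing-dependent LTD rule
#'
#' LTP credits presynaptic activity before the postsynaptic spike
#' (`pre_trace_before`, the usual EPSP trace); depression is driven by
#' presynaptic activity in a time-inversed window after it
#' (`pre_trace_after`):
#' `eta * (c * pre_trace_before * exp(-w) - scale * pre_trace_after)`.
#' For stationary inputs the equilibrium is the log-ratio of the
#' before/after presynaptic activity (plus `log(c)` and window constants),
#' i.e. the rule learns the contrast between the pattern that caused firing
#' and the activity that follows it.
#'
#' @param w Current weight(s).
#' @param pre_trace_before EPSP trace at the postsynaptic spike.
#' @param pre_trace_after Time-inversed-kernel trace of presynaptic spikes
#'   after the postsynaptic spike.
#' @param eta Learning rate.
#' @param c Offset constant.
#' @param scale Depression scale factor.
#' @return Net update(s) `dw`.
#' @export
ltd_variant_apply <- function(w, pre_trace_before, pre_trace_after, eta,
                              c = 1, scale = 1) {
  eta * (c * pre_trace_before * exp(-w) - scale * pre_trace_after)
}

#' Moment tracker for adaptive learning rates
#'
#' Running exponentially-decaying first (`S`) and second (`Q`) moments of
#' each weight, updated at each postsynaptic spike with the synapse's own
#' current rate: `S <- (1 - eta) S + eta w`, `Q <- (1 - eta) Q + eta w^2`.
#'
#' @param w Initial weight matrix or vector.
#' @param spread Initial variance ascribed to the weights; sets the initial
#'   adaptive rate high so early learning is fast.
#' @return A list with entries `S` and `Q` of the same shape as `w`.
#' @export
moment_tracker <- function(w, spread = 0.25) {
  list(S = w, Q = w^2 + spread)
}

#' Variance-tracking adaptive learning rate
#'
#' For a weight that has converged onto a log of a Beta-distributed
#' frequency estimate with effective sample size `N`, the variance of `w`
#' is approximately `(1 - p) / (p N)` with `p = exp(w - log c)`. Inverting
#' this gives the rate estimate
#' `eta = (Q - S^2) * p_hat / (1 - p_hat)` with `p_hat = exp(S - log c)`,
#' clipped to `[eta_min, eta_max]`. The estimate decays like `1/N` as
#' evidence accumulates and rises again when the weight drifts
#' (non-stationary input), supporting reorganization.
#'
#' If `p_hat >= 1` (a non-probability weight after removing the offset)
#' the rate falls back to `eta_min` with a warning.
#'
#' @param tracker A [moment_tracker()].
#' @param eta_min,eta_max Clip bounds.
#' @param c Offset constant to remove from the first moment.
#' @param warn Emit a warning on `p_hat >= 1` (default TRUE; the simulation
#'   loop counts these events in its diagnostics instead).
#' @return Learning rate(s), same shape as `tracker$S`.
#' @export
variance_tracking_rate <- function(tracker, eta_min = 1e-4, eta_max = 0.05,
                                   c = 1, warn = TRUE) {
  p <- exp(tracker$S - log(c))
  bad <- p >= 1
  if (any(bad) && warn) {
    warning("first-moment weight at or above 0 after offset removal; using eta_min")
  }
  v <- tracker$Q - tracker$S^2
  eta <- ifelse(bad, eta_min, v * p / (1 - p))
  pmin(pmax(eta, eta_min), eta_max)
}

update_tracker <- function(tracker, w, eta) {
  tracker$S <- (1 - eta) * tracker$S + eta * w
  tracker$Q <- (1 - eta) * tracker$Q + eta * w^2
  tracker
}
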