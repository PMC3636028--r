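#' Stochastic WTA network state
#'
#' Creates the state of a winner-take-all circuit of `K` stochastic spiking
#' output neurons driven by `n_inputs` channels: a weight matrix `w[k, i]`,
#' excitabilities `b[k]`, and bookkeeping for EPSP traces and inhibition.
#'
#' Weights are initialized i.i.d. uniform in
#' `[log(offset_c) - 3, log(offset_c) - 0.5]` (inside the admissible
#' log-probability regime, shifted by the positive-weight offset `c`) and
#' excitabilities at `log(1/K)`, which breaks the symmetry between neurons.
#'
#' @param K Number of output neurons.
#' @param n_inputs Number of input channels.
#' @param offset_c Positive weight offset constant `c = exp(w0)`; weights
#'   converge to `log P(...) + log(c)`, so `c > 1` shifts them positive.
#' @param weights,excitabilities Optional explicit initial values.
#' @return An object of class `wta_network` with fields `weights`
#'   (`K x n_inputs`), `excitabilities` (length `K`), and `offset_c`.
#' @examples
#' set.seed(1)
#' net <- wta_network(K = 3, n_inputs = 8)
#' dim(net$weights)
#' @export
wta_network <- function(K, n_inputs, offset_c = 1,
                        weights = NULL, excitabilities = NULL) {
  stopifnot(K >= 1, n_inputs >= 1, offset_c > 0)
  lc <- log(offset_c)
  if (is.null(weights)) {
    weights <- matrix(stats::runif(K * n_inputs, lc - 3, lc - 0.5),
                      nrow = K, ncol = n_inputs)
  }
  if (is.null(excitabilities)) excitabilities <- rep(log(1 / K), K)
  stopifnot(is.matrix(weights), nrow(weights) == K,
            ncol(weights) == n_inputs,
            length(excitabilities) == K,
            all(is.finite(weights)), all(is.finite(excitabilities)))
  structure(
    list(weights = weights, excitabilities = as.numeric(excitabilities),
         K = as.integer(K), n_inputs = as.integer(n_inputs),
         offset_c = offset_c),
    class = "wta_network"
  )
}

#' @export
print.wta_network <- function(x, ...) {
  cat(sprintf("<wta_network> K = %d output neurons, %d input channels, offset c = %g\n",
              x$K, x$n_inputs, x$offset_c))
  cat(sprintf("  priors exp(b)/sum: %s\n",
              paste(sprintf("%.3f", softmax(x$excitabilities)), collapse = " ")))
  invisible(x)
}

#' Membrane potential of one output neuron
#'
#' `u_k = sum_i w[k, i] * ytilde[i] + b[k] - I`.
#'
#' @param network A [wta_network()].
#' @param k Output neuron index.
#' @param traces Nonnegative trace vector `ytilde` (length `n_inputs`).
#' @param inhibition Common inhibition value `I(t)` (scalar, default 0).
#' @return The membrane potential (scalar).
#' @export
membrane_potential <- function(network, k, traces, inhibition = 0) {
  if (k < 1 || k > network$K) stop("invalid output neuron index")
  stopifnot(length(traces) == network$n_inputs)
  sum(network$weights[k, ] * traces) + network$excitabilities[k] - inhibition
}

softmax <- function(u) {
  e <- exp(u - max(u))
  e / sum(e)
}

#' Relative firing probabilities of the WTA circuit
#'
#' Given membrane potentials `u`, returns
#' `q_k = exp(u_k) / sum_l exp(u_l)` — the probability that the next circuit
#' spike originates from neuron `k`. Numerically stabilized by subtracting
#' `max(u)`, which also makes the result invariant to any common additive
#' signal such as the inhibition.
#'
#' @param u Finite numeric vector of membrane potentials.
#' @return Probability vector summing to 1.
#' @export
relative_firing_probabilities <- function(u) {
  if (length(u) == 0L) stop("empty membrane-potential vector")
  stopifnot(all(is.finite(u)))
  softmax(u)
}

#' Simulation configuration
#'
#' @param dt Time step in ms.
#' @param duration Simulated duration in ms; `NULL` (default) runs for
#'   the input train's duration.
#' @param firing_mode `"independent_poisson"` (each neuron spikes
#'   independently with probability `1 - exp(-rate_k * dt)`) or
#'   `"rate_rescaled_sampling"` (circuit spikes drawn from a Poisson process
#'   with the total rate, identities from the softmax). The two modes agree
#'   in winner-identity distribution.
#' @param r0 Rate scale: neuron `k` fires at `r0 * exp(u_k)` Hz. The
#'   exponential-firing model fixes rates only up to this proportionality
#'   constant.
#' @param u_max Membrane potentials are clipped to `[-u_max, u_max]` before
#'   exponentiation (benign: the softmax is shift-invariant).
#' @param seed Optional RNG seed applied at the start of [run_simulation()].
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dt = 1, duration = NULL,
                       firing_mode = c("independent_poisson",
                                       "rate_rescaled_sampling"),
                       r0 = 1, u_max = 30, seed = NULL) {
  firing_mode <- match.arg(firing_mode)
  stopifnot(dt > 0, is.null(duration) || duration >= 0, r0 > 0, u_max > 0)
  structure(
    list(dt = dt, duration = duration, firing_mode = firing_mode,
         r0 = r0, u_max = u_max, seed = seed),
    class = "sim_config"
  )
}

#' Advance the WTA circuit by one time step
#'
#' Single-step reference semantics of the simulator: given the current
#' traces and inhibition, clip and exponentiate membrane potentials, and
#' draw output spikes for the interval `[t, t + dt)`.
#'
#' A warning is issued when any per-neuron spiking probability exceeds 0.2
#' per step (the discretization then distorts the Poisson statistics).
#'
#' @param network A [wta_network()].
#' @param traces Trace vector `ytilde` at time `t`.
#' @param inhibition Common inhibition `I(t)`.
#' @param config A [sim_config()].
#' @return Integer vector of the output neurons that spiked in this step
#'   (possibly empty; in `independent_poisson` mode at most one spike per
#'   neuron per step).
#' @export
wta_step <- function(network, traces, inhibition = 0, config = sim_config()) {
  u <- as.vector(network$weights %*% traces) + network$excitabilities -
    inhibition
  if (any(u > config$u_max)) {
    warning("membrane potential clipped at u_max before exponentiation")
  }
  u <- pmin(pmax(u, -config$u_max), config$u_max)
  rate_ms <- config$r0 * exp(u) / 1000  # spikes per ms
  if (config$firing_mode == "independent_poisson") {
    p <- -expm1(-rate_ms * config$dt)
    if (max(p) > 0.2) {
      warning("per-step firing probability exceeds 0.2; reduce dt")
    }
    which(stats::runif(length(p)) < p)
  } else {
    n <- stats::rpois(1L, sum(rate_ms) * config$dt)
    if (n == 0L) integer() else
      sample.int(network$K, n, replace = TRUE, prob = softmax(u))
  }
}

#' Initialize a WTA network at the average-input model
#'
#' Sets every weight to the log of the channel's expected EPSP trace under
#' the input train's empirical firing rates (plus the offset `log(c)` and
#' a small symmetric jitter), and excitabilities to `log(1/K)`. All
#' neurons then start as copies of the global average-input model: no
#' neuron holds a systematic likelihood advantage, so early competition is
#' decided by input-specific fluctuations, and the weight-dependent STDP
#' rule grows exactly those differences into specialized models. Starting
#' far from the average-input statistics instead hands the first neuron
#' that adapts a global advantage proportional to the input
#' dimensionality, which silences its competitors permanently.
#'
#' The expected stationary trace is `rate * integral(eps)` for the
#' additive alpha kernel and `1 - exp(-rate * sigma)` (the window
#' occupancy) for the rectangular kernel.
#'
#' @param K Number of output neurons.
#' @param input A [spike_train()] whose empirical channel rates seed the
#'   weights.
#' @param kernel The [kernel_spec()] that will be used in simulation.
#' @param offset_c Positive weight offset constant.
#' @param jitter Half-width of the uniform symmetric jitter added to each
#'   weight (log scale).
#' @param rate_floor_hz Channels quieter than this are treated as firing
#'   at this rate (avoids `log(0)` for silent channels).
#' @param prototypes Optional `K x n` matrix of per-channel firing rates
#'   (Hz), one prototype stimulus per neuron (e.g. the rates encoding a
#'   randomly drawn training example). Each neuron is then seeded at the
#'   model of `prototype_mix` parts its prototype and `1 - prototype_mix`
#'   parts the global average — the spiking analogue of seeding a mixture
#'   fit at random data points, which spreads the neurons' initial
#'   footholds over the stimulus family instead of leaving them all at
#'   the average model.
#' @param prototype_mix Mixing proportion of the prototype rates.
#' @return A [wta_network()].
#' @export
wta_network_from_input <- function(K, input, kernel = kernel_spec("alpha"),
                                   offset_c = 1, jitter = 0.1,
                                   rate_floor_hz = 0.1,
                                   prototypes = NULL,
                                   prototype_mix = 0.5) {
  n <- n_channels(input)
  dur <- train_duration(input)
  rate_ms <- pmax(tabulate(input$channel, nbins = n) / dur,
                  rate_floor_hz / 1000)
  trace_of <- function(r_ms) {
    if (kernel$kind == "alpha") {
      r_ms * alpha_amplitude(kernel) *
        (kernel$tau_decay - kernel$tau_rise)
    } else {
      -expm1(-r_ms * kernel$sigma)
    }
  }
  if (is.null(prototypes)) {
    W <- matrix(rep(log(trace_of(rate_ms)), each = K), K, n)
  } else {
    stopifnot(is.matrix(prototypes), nrow(prototypes) == K,
              ncol(prototypes) == n)
    mix_ms <- (1 - prototype_mix) * rep(rate_ms, each = K) +
      prototype_mix * pmax(prototypes, rate_floor_hz) / 1000
    W <- log(trace_of(matrix(mix_ms, K, n)))
  }
  W <- W + log(offset_c) + stats::runif(K * n, -jitter, jitter)
  wta_network(K, n, offset_c = offset_c, weights = W)
}
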