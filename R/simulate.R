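#' Run a WTA circuit simulation
#'
#' Time-stepped simulation of the stochastic WTA circuit on an input spike
#' train: EPSP traces are advanced incrementally (for the alpha kernel via
#' two exponential state variables per channel, which reproduces the direct
#' convolution exactly at step boundaries), membrane potentials are formed
#' as `u_k = sum_i w[k,i] ytilde_i + b_k - I(t)`, output spikes are drawn
#' from the exponential firing model, and — when a
#' [plasticity_config()] is supplied — STDP and intrinsic plasticity are
#' applied at every circuit spike.
#'
#' Within a step, input spikes are applied at their exact times (their
#' kernel contribution is evaluated at the step end), at most one output
#' spike per neuron per step is drawn in `independent_poisson` mode, and
#' multiple circuit spikes in one step trigger sequential plasticity
#' updates.
#'
#' @param input A [spike_train()] with `n_channels(input) ==
#'   network$n_inputs`.
#' @param network A [wta_network()]; returned updated when learning is on.
#' @param config A [sim_config()]. If `config$duration` is `NULL` the
#'   input train's duration is used.
#' @param plasticity A [plasticity_config()] to learn, or `NULL` to freeze
#'   all parameters.
#' @param inhibition An [inhibition_config()].
#' @param kernel A [kernel_spec()] for the input EPSPs.
#' @param checkpoint_every Interval in ms between trajectory checkpoints
#'   (`Inf` = none).
#' @param checkpoint_weights Store the full weight matrix at checkpoints
#'   (otherwise only time and excitabilities).
#' @return A list of class `sem_run` with elements:
#'   \describe{
#'     \item{output}{[spike_train()] of output spikes (channels = neurons)}
#'     \item{network}{the final [wta_network()]}
#'     \item{trajectory}{list of checkpoints}
#'     \item{diagnostics}{step counts, output rate, clip/warning counters}
#'   }
#' @export
run_simulation <- function(input, network, config = sim_config(),
                           plasticity = NULL,
                           inhibition = inhibition_config(),
                           kernel = kernel_spec("alpha"),
                           checkpoint_every = Inf,
                           checkpoint_weights = FALSE) {
  if (n_channels(input) != network$n_inputs) {
    stop("input channel count does not match network n_inputs")
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  dt <- config$dt
  duration <- if (is.null(config$duration)) train_duration(input) else
    config$duration
  n_steps <- floor(duration / dt + 1e-9)
  K <- network$K; n <- network$n_inputs
  W <- network$weights; b <- network$excitabilities
  learn <- !is.null(plasticity)
  indep <- config$firing_mode == "independent_poisson"
  log_r0 <- log(config$r0)
  log_target_ms <- log(inhibition$target_output_rate_hz / 1000)

  # --- input spikes binned by step ------------------------------------
  istep <- pmin(floor(input$time / dt) + 1L, n_steps)
  keep <- input$time < n_steps * dt
  sp_t <- input$time[keep]; sp_ch <- input$channel[keep]
  istep <- istep[keep]
  cnt <- tabulate(istep, nbins = n_steps)
  ends <- cumsum(cnt)

  # --- trace state ----------------------------------------------------
  alpha <- kernel$kind == "alpha"
  if (alpha) {
    A <- alpha_amplitude(kernel)
    dec_d <- exp(-dt / kernel$tau_decay)
    dec_r <- exp(-dt / kernel$tau_rise)
    yd <- numeric(n); yr <- numeric(n)
  } else {
    last_in <- rep(-Inf, n)
  }

  # --- plasticity state -----------------------------------------------
  if (learn) {
    cc <- plasticity$offset_c
    ltd <- plasticity$rule == "timing_dependent_ltd"
    simple <- plasticity$rule == "simple"
    if (plasticity$adaptive) {
      trk_w <- moment_tracker(W, spread = plasticity$init_spread)
    }
    if (ltd) {
      post_trace <- numeric(K)
      dec_ltd <- exp(-dt / plasticity$ltd_tau)
    }
  }

  # --- inhibition state -----------------------------------------------
  ou <- inhibition$ou_mu
  last_spike <- NA_real_
  has_ou <- inhibition$ou_sigma > 0 || inhibition$ou_mu != 0
  has_osc <- inhibition$osc_amplitude > 0
  balance <- inhibition$balance == "exact"

  # --- output / diagnostics buffers -----------------------------------
  cap <- 4096L
  out_t <- numeric(cap); out_k <- integer(cap); n_out <- 0L
  n_clip <- 0L; n_fastp <- 0L; n_eta_fallback <- 0L
  trajectory <- list()
  next_ckpt <- if (is.finite(checkpoint_every)) checkpoint_every else Inf
  take_ckpt <- function(t_now) {
    ck <- list(time = t_now, excitabilities = b)
    if (checkpoint_weights) ck$weights <- W
    ck
  }

  p0 <- 1L
  for (s in seq_len(n_steps)) {
    t_end <- s * dt
    # trace decay + this step's input spikes
    if (alpha) {
      yd <- yd * dec_d; yr <- yr * dec_r
    }
    p1 <- ends[s]
    if (p1 >= p0) {
      idx <- p0:p1
      ch <- sp_ch[idx]
      if (alpha) {
        ed <- exp(-(t_end - sp_t[idx]) / kernel$tau_decay)
        er <- exp(-(t_end - sp_t[idx]) / kernel$tau_rise)
        if (anyDuplicated(ch)) {
          for (j in seq_along(ch)) {
            yd[ch[j]] <- yd[ch[j]] + ed[j]
            yr[ch[j]] <- yr[ch[j]] + er[j]
          }
        } else {
          yd[ch] <- yd[ch] + ed
          yr[ch] <- yr[ch] + er
        }
      } else {
        last_in[ch] <- sp_t[idx]
      }
      # timing-dependent LTD: depression credited at presynaptic spikes,
      # driven by the decaying trace of recent postsynaptic firing
      if (learn && ltd && any(post_trace > 0)) {
        for (i in unique(ch)) {
          nrep <- sum(ch == i)
          eta_i <- if (plasticity$adaptive) {
            variance_tracking_rate(
              list(S = trk_w$S[, i], Q = trk_w$Q[, i]),
              plasticity$eta_min, plasticity$eta_max, cc, warn = FALSE)
          } else plasticity$eta
          W[, i] <- W[, i] -
            nrep * eta_i * plasticity$ltd_scale * post_trace
        }
      }
      p0 <- p1 + 1L
    }
    yt <- if (alpha) A * (yd - yr) else
      as.numeric(t_end - last_in < kernel$sigma)

    # membrane potentials and inhibition
    u_exc <- as.vector(W %*% yt) + b
    I <- 0
    if (balance) {
      mx <- max(u_exc)
      I <- mx + log(sum(exp(u_exc - mx))) + log_r0 - log_target_ms -
        log(1000)
    }
    if (!is.na(last_spike) && inhibition$reset_amplitude > 0) {
      I <- I + inhibition$reset_amplitude *
        exp(-(t_end - last_spike) / inhibition$reset_tau)
    }
    if (has_ou) {
      ou <- ou_step(ou, dt, inhibition$ou_theta, inhibition$ou_mu,
                    inhibition$ou_sigma)
      I <- I + ou
    }
    if (has_osc) {
      I <- I - oscillation_signal(t_end, inhibition$osc_amplitude,
                                  inhibition$osc_freq_hz,
                                  inhibition$osc_phase)
    }
    u <- u_exc - I
    if (any(u > config$u_max)) n_clip <- n_clip + 1L
    u <- pmin(pmax(u, -config$u_max), config$u_max)
    rate_ms <- config$r0 * exp(u) / 1000

    # output spikes
    if (indep) {
      p <- -expm1(-rate_ms * dt)
      if (max(p) > 0.2) n_fastp <- n_fastp + 1L
      fired <- which(stats::runif(K) < p)
    } else {
      nsp <- stats::rpois(1L, sum(rate_ms) * dt)
      fired <- if (nsp == 0L) integer() else
        sample.int(K, nsp, replace = TRUE, prob = softmax(u))
    }

    if (length(fired)) {
      for (k in fired) {
        if (learn) {
          # synaptic update for the firing neuron's row
          tr <- if (simple) as.numeric(yt > 0) else yt
          wk <- W[k, ]
          if (plasticity$adaptive) {
            eta_k <- variance_tracking_rate(
              list(S = trk_w$S[k, ], Q = trk_w$Q[k, ]),
              plasticity$eta_min, plasticity$eta_max, cc, warn = FALSE)
            n_eta_fallback <- n_eta_fallback +
              as.integer(any(trk_w$S[k, ] >= log(cc)))
          } else eta_k <- plasticity$eta
          dw <- if (ltd) eta_k * (cc * tr * exp(-wk)) else
            eta_k * (cc * tr * exp(-wk) - 1)
          dw <- pmin(pmax(dw, -plasticity$delta_max),
                     plasticity$delta_max)
          wk <- pmax(wk + dw, log(cc) + plasticity$w_min_rel)
          W[k, ] <- wk
          if (plasticity$adaptive) {
            trk_w$S[k, ] <- (1 - eta_k) * trk_w$S[k, ] + eta_k * wk
            trk_w$Q[k, ] <- (1 - eta_k) * trk_w$Q[k, ] + eta_k * wk^2
          }
          # intrinsic plasticity: every neuron, at every circuit spike
          eta_b <- plasticity$eta_b
          db <- ifelse(seq_len(K) == k, eta_b * (exp(-b) - 1), -eta_b)
          db <- pmin(pmax(db, -plasticity$delta_max),
                     plasticity$delta_max)
          b <- pmax(b + db, plasticity$w_min_rel)
          if (ltd) post_trace[k] <- post_trace[k] + 1
        }
        n_out <- n_out + 1L
        if (n_out > cap) {
          cap <- cap * 2L
          out_t <- c(out_t, numeric(cap / 2L))
          out_k <- c(out_k, integer(cap / 2L))
        }
        out_t[n_out] <- t_end
        out_k[n_out] <- k
      }
      last_spike <- t_end
    }
    if (learn && ltd) post_trace <- post_trace * dec_ltd

    if (t_end >= next_ckpt) {
      trajectory[[length(trajectory) + 1L]] <- take_ckpt(t_end)
      next_ckpt <- next_ckpt + checkpoint_every
    }
  }

  net_out <- network
  net_out$weights <- W
  net_out$excitabilities <- b
  structure(
    list(
      output = spike_train(out_t[seq_len(n_out)], out_k[seq_len(n_out)],
                           n_channels = K, duration = n_steps * dt),
      network = net_out,
      trajectory = trajectory,
      diagnostics = list(
        n_steps = n_steps,
        n_output_spikes = n_out,
        output_rate_hz = 1000 * n_out / max(n_steps * dt, 1e-12),
        n_potential_clips = n_clip,
        n_fast_prob_steps = n_fastp,
        n_eta_fallbacks = n_eta_fallback
      )
    ),
    class = "sem_run"
  )
}

#' @export
print.sem_run <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf("<sem_run> %d steps, %d output spikes (%.1f Hz total)\n",
              d$n_steps, d$n_output_spikes, d$output_rate_hz))
  invisible(x)
}
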