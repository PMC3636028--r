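#' Per-group weight normalization summary
#'
#' At the equilibria of the plasticity rules the weights satisfy
#' `sum_{i in G_j} exp(w_ki - log c) = 1` for every neuron and group, and
#' `sum_k exp(b_k) = 1` — normalization emerges rather than being
#' enforced. When a fraction `missing_rate` of group readings is missing
#' (the same for every group), all weights carry the constant offset
#' `log(1 - missing_rate)`, which is divided out here. When windows can
#' straddle two patterns, pass the measured per-group `occupancy`
#' (see [estimate_group_occupancy()]): the group sums converge to the
#' expected number of in-window active channels, not to `1 - missing`.
#'
#' @param network A [wta_network()].
#' @param code A [population_code()].
#' @param missing_rate Estimated missing-value rate to correct for.
#' @param occupancy Optional expected in-window occupancy (scalar or one
#'   value per group); overrides `missing_rate` when given.
#' @return List with `group_sums` (`K x n_groups` matrix of corrected
#'   per-group weight sums) and `prior_sum` (`sum_k exp(b_k)`).
#' @export
emergent_normalization <- function(network, code, missing_rate = 0,
                                   occupancy = NULL) {
  stopifnot(all(missing_rate >= 0), all(missing_rate < 1))
  if (is.null(occupancy)) occupancy <- 1 - missing_rate
  stopifnot(length(occupancy) %in% c(1L, code$n_groups),
            all(occupancy > 0))
  W <- network$weights - log(network$offset_c)
  gs <- vapply(seq_len(code$n_groups), function(j) {
    rowSums(exp(W[, group_channels(code, j), drop = FALSE]))
  }, numeric(network$K))
  gs <- matrix(gs, nrow = network$K)
  gs <- sweep(gs, 2, rep(occupancy, length.out = code$n_groups), "/")
  list(group_sums = gs,
       prior_sum = sum(exp(network$excitabilities)))
}

#' Expected output activity per test pattern
#'
#' Presents each encoded pattern with frozen weights and accumulates the
#' relative firing probabilities (softmax of the excitatory drives; the
#' common inhibition cancels) over the presentation — the deterministic
#' expected spike share per neuron, as used for winner maps.
#'
#' @param network A [wta_network()].
#' @param patterns Evidence matrix (`n x n_groups`).
#' @param code A [population_code()].
#' @param kernel A [kernel_spec()].
#' @param active_rate_hz,pattern_ms,gap_ms Encoding parameters.
#' @param dt Step in ms.
#' @return `n x K` matrix of accumulated firing probabilities.
#' @export
expected_activity <- function(network, patterns, code,
                              kernel = kernel_spec("alpha"),
                              active_rate_hz = 20, pattern_ms = 50,
                              gap_ms = 10, dt = 1) {
  n <- nrow(patterns)
  out <- matrix(0, n, network$K)
  for (i in seq_len(n)) {
    tr <- encode_stream(patterns[i, , drop = FALSE], code,
                        active_rate_hz = active_rate_hz,
                        pattern_ms = pattern_ms, gap_ms = gap_ms)
    steps <- floor((pattern_ms + gap_ms) / dt)
    acc <- numeric(network$K)
    if (kernel$kind == "alpha") {
      A <- alpha_amplitude(kernel)
      yd <- numeric(code$n_channels); yr <- yd
      dec_d <- exp(-dt / kernel$tau_decay)
      dec_r <- exp(-dt / kernel$tau_rise)
      for (s in seq_len(steps)) {
        t_end <- s * dt
        yd <- yd * dec_d; yr <- yr * dec_r
        sel <- tr$time > t_end - dt & tr$time <= t_end
        if (any(sel)) {
          ch <- tr$channel[sel]
          yd[ch] <- yd[ch] + exp(-(t_end - tr$time[sel]) / kernel$tau_decay)
          yr[ch] <- yr[ch] + exp(-(t_end - tr$time[sel]) / kernel$tau_rise)
        }
        u <- as.vector(network$weights %*% (A * (yd - yr))) +
          network$excitabilities
        acc <- acc + softmax(u)
      }
    } else {
      last <- rep(-Inf, code$n_channels)
      for (s in seq_len(steps)) {
        t_end <- s * dt
        sel <- tr$time > t_end - dt & tr$time <= t_end
        if (any(sel)) last[tr$channel[sel]] <- t_end
        yt <- as.numeric(t_end - last < kernel$sigma)
        u <- as.vector(network$weights %*% yt) + network$excitabilities
        acc <- acc + softmax(u)
      }
    }
    out[i, ] <- acc
  }
  out
}

#' Hidden-cause discovery on Gaussian-blob images
#'
#' Trains a `K`-neuron WTA circuit on a population-coded stream of
#' Gaussian-blob images with unequal cause priors, with a rectangular
#' integration window matching the presentation, and reports the learned
#' priors, the normalized-conditional-entropy trajectory, the weight
#' normalization summary (missing-value corrected), and the learned
#' weight images.
#'
#' @param duration_s Training duration in simulated seconds.
#' @param K Number of output neurons.
#' @param priors Generator cause priors.
#' @param active_rate_hz Encoding rate (Hz).
#' @param pattern_ms,gap_ms Presentation and gap durations (ms).
#' @param sigma Integration window (ms); also the rectangular EPSP length.
#' @param oscillation Add a 20 Hz background oscillation (relative
#'   amplitude 0.5) to input rates and membrane potentials, preserving
#'   average rates.
#' @param n_entropy_patterns Held-out images used for each entropy
#'   evaluation.
#' @param checkpoint_every Entropy-trajectory checkpoint interval (ms).
#' @param target_rate_hz Circuit output rate enforced by the inhibition.
#' @param plasticity A [plasticity_config()].
#' @param seed RNG seed.
#' @return List of class `example1_report` with the learned network,
#'   priors, entropy trajectory, normalization summary and diagnostics.
#' @export
run_example1 <- function(duration_s = 150, K = 4,
                         priors = c(0.1, 0.2, 0.3, 0.4),
                         active_rate_hz = 25, pattern_ms = 40,
                         gap_ms = 10, sigma = 40,
                         oscillation = FALSE,
                         n_entropy_patterns = 300,
                         checkpoint_every = 5e3,
                         target_rate_hz = 100,
                         plasticity = plasticity_config(
                           "complex", eta_min = 2e-3),
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cycle <- pattern_ms + gap_ms
  n_images <- ceiling(duration_s * 1000 / cycle)
  ds <- gaussian_blob_dataset(n_images + n_entropy_patterns,
                              priors = priors)
  train_idx <- seq_len(n_images)
  test_idx <- n_images + seq_len(n_entropy_patterns)
  osc_a <- if (oscillation) 0.5 else 0
  stream <- encode_stream(ds$patterns[train_idx, , drop = FALSE], ds$code,
                          active_rate_hz = active_rate_hz,
                          pattern_ms = pattern_ms, gap_ms = gap_ms,
                          osc_amplitude = osc_a)
  kernel <- kernel_spec("rectangular_renewable", sigma = sigma)
  net <- wta_network_from_input(K, stream, kernel = kernel,
                                offset_c = plasticity$offset_c)
  inh <- inhibition_config(target_output_rate_hz = target_rate_hz,
                           osc_amplitude = if (oscillation) 1 else 0)
  run <- run_simulation(stream, net, sim_config(dt = 1),
                        plasticity = plasticity, inhibition = inh,
                        kernel = kernel,
                        checkpoint_every = checkpoint_every,
                        checkpoint_weights = TRUE)
  # entropy trajectory from checkpointed models
  test_pat <- ds$patterns[test_idx, , drop = FALSE]
  test_lab <- ds$labels[test_idx]
  entropy_of <- function(W, b) {
    model <- weights_to_model(W, ds$code, excitabilities = b)
    post <- t(apply(test_pat, 1, function(ev) posterior(model, ev)))
    normalized_conditional_entropy(test_lab, post)
  }
  ck_keep <- run$trajectory[seq(1, length(run$trajectory), by = 2)]
  traj <- data.frame(
    time_ms = c(0, vapply(ck_keep, `[[`, numeric(1), "time")),
    entropy = c(entropy_of(net$weights, net$excitabilities),
                vapply(ck_keep, function(ck) {
                  entropy_of(ck$weights, ck$excitabilities)
                }, numeric(1)))
  )
  # time-averaged equilibrium statistics (Polyak-style): average exp(w)
  # and the prior estimates over the final 50 s of checkpoints to remove
  # the stochastic-equilibrium fluctuation of individual snapshots
  tail_ck <- Filter(function(ck) ck$time > n_images * cycle - 50e3,
                    run$trajectory)
  avg_w <- Reduce(`+`, lapply(tail_ck, `[[`, "weights")) /
    length(tail_ck)
  avg_priors <- Reduce(`+`, lapply(tail_ck, function(ck) {
    softmax(ck$excitabilities)
  })) / length(tail_ck)
  avg_net <- run$network
  avg_net$weights <- avg_w
  miss <- estimate_missing_rate(stream, ds$code, sigma)
  occup <- estimate_group_occupancy(stream, ds$code, sigma,
                                    per_group = TRUE)
  # the equilibrium of the synaptic rule is w -> log P(channel active
  # in window | this neuron fires); the per-(neuron, group)
  # normalization offset is therefore the conditional occupancy at the
  # neuron's own spike times
  occ_spk <- occupancy_at_spikes(stream, run$output, ds$code, sigma, K)
  ck_keep <- run$trajectory[seq(1, length(run$trajectory), by = 2)]
  traj <- data.frame(
    time_ms = c(0, vapply(ck_keep, `[[`, numeric(1), "time")),
    entropy = c(entropy_of(net$weights, net$excitabilities),
                vapply(ck_keep, function(ck) {
                  entropy_of(ck$weights, ck$excitabilities)
                }, numeric(1)))
  )
  # time-averaged equilibrium statistics (Polyak-style): average exp(w)
  # and the prior estimates over the final 50 s of checkpoints to remove
  # the stochastic-equilibrium fluctuation of individual snapshots
  tail_ck <- Filter(function(ck) ck$time > n_images * cycle - 50e3,
                    run$trajectory)
  avg_w <- Reduce(`+`, lapply(tail_ck, `[[`, "weights")) /
    length(tail_ck)
  avg_priors <- Reduce(`+`, lapply(tail_ck, function(ck) {
    softmax(ck$excitabilities)
  })) / length(tail_ck)
  avg_net <- run$network
  avg_net$weights <- avg_w
  miss <- estimate_missing_rate(stream, ds$code, sigma)
  occup <- estimate_group_occupancy(stream, ds$code, sigma,
                                    per_group = TRUE)
  # the equilibrium of the synaptic rule is w -> log P(channel active in
  # window | this neuron fires); the per-(neuron, group) normalization
  # offset is therefore the empirical in-window group occupancy at the
  # neuron's own spike times, measured over the final training phase
  occ_spk <- {
    tail_t <- 0
    cnt <- matrix(0, K, ds$code$n_groups); nk <- numeric(K)
    sel_sp <- which(run$output$time >= tail_t)
    # balance the sample across neurons: low-prior neurons fire rarely
    # and would otherwise get a noisy occupancy estimate
    sel_sp <- unlist(lapply(seq_len(K), function(k) {
      sk <- sel_sp[run$output$channel[sel_sp] == k]
      if (length(sk) > 8000L) {
        sk[round(seq(1, length(sk), length.out = 8000L))]
      } else sk
    }))
    for (ii in sel_sp) {
      t <- run$output$time[ii]; k <- run$output$channel[ii]
      lo <- findInterval(t - sigma, stream$time) + 1L
      hi <- findInterval(t, stream$time)
      if (hi >= lo) {
        g <- tabulate(ds$code$group_of[unique(stream$channel[lo:hi])],
                      nbins = ds$code$n_groups)
        cnt[k, ] <- cnt[k, ] + g
      }
      nk[k] <- nk[k] + 1
    }
    pmax(cnt / pmax(nk, 1), 0.05)
  }
  learned_priors <- avg_priors
  # align neurons to generator causes by posterior mass
  model <- weights_to_model(run$network, ds$code)
  post <- t(apply(test_pat, 1, function(ev) posterior(model, ev)))
  confusion <- vapply(seq_len(K), function(l) {
    colSums(post[test_lab == l, , drop = FALSE])
  }, numeric(K))
  perm <- match_labels(matrix(confusion, K, K))
  structure(
    list(network = run$network, dataset_priors = priors,
         learned_priors = learned_priors,
         aligned_priors = learned_priors[order(perm)],
         neuron_to_cause = perm,
         entropy_trajectory = traj,
         missing_rate = miss, group_occupancy = occup,
         normalization = {
           nm <- emergent_normalization(avg_net, ds$code)
           nm$group_sums <- nm$group_sums / occ_spk
           nm
         },
         weight_images = lapply(seq_len(K), function(k) {
           img <- rep(NA_real_, ds$grid^2)
           on_ch <- channel_for(ds$code, seq_len(ncol(ds$images)), 1L)
           img[ds$permutation] <- run$network$weights[k, on_ch]
           matrix(img, ds$grid, ds$grid)
         }),
         oscillation = oscillation,
         diagnostics = run$diagnostics),
    class = "example1_report"
  )
}

#' Orientation-selectivity emergence on oriented bars
#'
#' Trains a `K`-neuron WTA circuit on population-coded noisy oriented-bar
#' images and maps the learned orientation preferences with noise-free
#' test bars.
#'
#' @param duration_s Training duration in simulated seconds.
#' @param K Number of output neurons.
#' @param flip_prob Pixel flip noise of the training bars.
#' @param active_rate_hz Encoding rate (Hz).
#' @param pattern_ms,gap_ms Presentation and gap durations (ms).
#' @param test_step_deg Angular resolution of the test sweep (degrees).
#' @param min_run_deg Minimum contiguous won angular range for a neuron to
#'   count as an oriented model (degrees).
#' @param min_sep_deg Minimum pairwise preferred-angle separation
#'   (degrees).
#' @param target_rate_hz Circuit output rate enforced by the inhibition.
#' @param plasticity A [plasticity_config()].
#' @param kernel EPSP kernel for training and testing.
#' @param seed RNG seed.
#' @return List of class `example2_report` with the winner map, preferred
#'   angles, the count of distinct oriented models, and the network.
#' @export
run_example2 <- function(duration_s = 200, K = 10, flip_prob = 0.02,
                         active_rate_hz = 20, pattern_ms = 50,
                         gap_ms = 10, test_step_deg = 0.5,
                         min_run_deg = 5, min_sep_deg = 5,
                         target_rate_hz = 100,
                         plasticity = plasticity_config("complex"),
                         kernel = kernel_spec("alpha"),
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cycle <- pattern_ms + gap_ms
  n_images <- ceiling(duration_s * 1000 / cycle)
  ds <- oriented_bar_dataset(n_images, flip_prob = flip_prob)
  stream <- encode_stream(ds$patterns, ds$code,
                          active_rate_hz = active_rate_hz,
                          pattern_ms = pattern_ms, gap_ms = gap_ms)
  # seed each neuron at a training image blended with the average;
  # images chosen by greedy max-dissimilarity so the footholds spread
  # over the stimulus family (uses only pixel values, not the angles)
  cand <- sample(nrow(ds$patterns), min(60L, nrow(ds$patterns)))
  on_mat <- ds$patterns[cand, , drop = FALSE] == 1L
  pick_idx <- 1L
  for (step in 2:K) {
    d <- vapply(seq_along(cand), function(i) {
      min(vapply(pick_idx, function(p) {
        sum(xor(on_mat[i, ], on_mat[p, ]))
      }, numeric(1)))
    }, numeric(1))
    pick_idx <- c(pick_idx, which.max(d))
  }
  pick <- cand[pick_idx]
  proto <- matrix(0, K, ds$code$n_channels)
  for (k in seq_len(K)) {
    ch <- channel_for(ds$code, seq_len(ds$code$n_groups),
                      ds$patterns[pick[k], ])
    proto[k, ch] <- active_rate_hz
  }
  net <- wta_network_from_input(K, stream, kernel = kernel,
                                offset_c = plasticity$offset_c,
                                prototypes = proto)
  inh <- inhibition_config(target_output_rate_hz = target_rate_hz,
                           reset_amplitude = 0)
  run <- run_simulation(stream, net, sim_config(dt = 1),
                        plasticity = plasticity, inhibition = inh,
                        kernel = kernel)
  test <- orientation_map(run$network, ds$grid, test_step_deg, kernel,
                          active_rate_hz, pattern_ms, gap_ms)
  sel <- orientation_selectivity(test$winner, test$angles, K,
                                 min_run_deg, min_sep_deg)
  structure(
    c(list(network = run$network, diagnostics = run$diagnostics), test,
      sel),
    class = "example2_report"
  )
}

#' Winner map over noise-free test bars
#'
#' @param network A trained [wta_network()].
#' @param grid Image grid side.
#' @param step_deg Angular step of the sweep.
#' @param kernel,active_rate_hz,pattern_ms,gap_ms Test encoding.
#' @return List with `angles`, `winner` (neuron per angle) and `activity`
#'   (the full angle x K expected-activity matrix).
#' @export
orientation_map <- function(network, grid = 28L, step_deg = 0.5,
                            kernel = kernel_spec("alpha"),
                            active_rate_hz = 20, pattern_ms = 50,
                            gap_ms = 10) {
  angles <- seq(0, 180 - step_deg, by = step_deg)
  pats <- t(vapply(angles, function(a) {
    ifelse(as.vector(oriented_bar_image(a, grid = grid,
                                        flip_prob = 0)) == 1L, 1L, 2L)
  }, integer(grid^2)))
  code <- binary_code(grid^2)
  act <- expected_activity(network, pats, code, kernel, active_rate_hz,
                           pattern_ms, gap_ms)
  list(angles = angles, winner = apply(act, 1, which.max),
       activity = act)
}

#' Count distinct oriented models in a winner map
#'
#' A neuron counts as a distinct oriented model when it wins a contiguous
#' (circularly, modulo 180 degrees) run of at least `min_run_deg` of test
#' angles and its preferred angle (circular mean of won angles in
#' orientation space) is at least `min_sep_deg` away from every other
#' counted neuron's.
#'
#' @param winner Winning neuron per test angle.
#' @param angles Test angles in degrees.
#' @param K Number of neurons.
#' @param min_run_deg,min_sep_deg Selectivity criteria in degrees.
#' @return List with `n_selective`, `preferred_angles` (NA for neurons
#'   that never win), `run_deg` (longest contiguous won run per neuron).
#' @export
orientation_selectivity <- function(winner, angles, K, min_run_deg = 5,
                                    min_sep_deg = 5) {
  step <- diff(angles[1:2])
  n <- length(angles)
  run_deg <- numeric(K)
  pref <- rep(NA_real_, K)
  for (k in seq_len(K)) {
    won <- winner == k
    if (!any(won)) next
    # longest circular run of TRUE
    x <- c(won, won)
    best <- 0L; cur <- 0L
    for (i in seq_along(x)) {
      cur <- if (x[i]) cur + 1L else 0L
      best <- max(best, cur)
    }
    run_deg[k] <- min(best, n) * step
    th <- 2 * angles[won] * pi / 180
    pref[k] <- (atan2(mean(sin(th)), mean(cos(th))) * 180 / pi / 2) %% 180
  }
  cand <- which(run_deg >= min_run_deg)
  ok <- rep(FALSE, K)
  ok[cand] <- TRUE
  circ_dist <- function(a, b) {
    d <- abs(a - b) %% 180
    pmin(d, 180 - d)
  }
  for (k in cand) {
    for (o in setdiff(cand, k)) {
      # pairwise conflicts disqualify the smaller territory
      # (ties: the higher index)
      if (circ_dist(pref[k], pref[o]) < min_sep_deg &&
          (run_deg[k] < run_deg[o] ||
           (run_deg[k] == run_deg[o] && k > o))) {
        ok[k] <- FALSE
      }
    }
  }
  list(n_selective = sum(ok), preferred_angles = pref, run_deg = run_deg,
       selective = ok)
}

#' Spatio-temporal spike-pattern detection
#'
#' Trains a `K`-neuron WTA circuit on a stream with embedded frozen
#' Poisson spike patterns, then freezes the weights and counts, on a
#' held-out stream with the same frozen patterns but fresh noise and
#' ordering, the neurons that specialize on a single pattern.
#'
#' A neuron is specialized when at least `spec_frac` of its held-out
#' spikes fall inside intervals of one pattern id and no other neuron
#' claims that id.
#'
#' @param train_duration_s,test_duration_s Stream lengths in seconds.
#' @param K Number of output neurons.
#' @param n_channels,n_patterns,pattern_len_ms Stream geometry.
#' @param spec_frac Specialization threshold on the spike fraction.
#' @param target_rate_hz Circuit output rate enforced by the inhibition.
#' @param plasticity A [plasticity_config()].
#' @param kernel EPSP kernel (alpha, 1 ms rise / 15 ms decay, by
#'   default).
#' @param seed RNG seed.
#' @return List of class `example4_report` with `n_specialized`,
#'   per-neuron claimed pattern and spike fractions, the noise neuron's
#'   noise-spike fraction, and the trained network.
#' @export
run_example4 <- function(train_duration_s = 200, test_duration_s = 50,
                         K = 6, n_channels = 500L, n_patterns = 5L,
                         pattern_len_ms = 50, spec_frac = 0.6,
                         target_rate_hz = 50,
                         plasticity = plasticity_config(
                           "complex", eta = 0.02, eta_b = 1e-5),
                         kernel = kernel_spec("alpha"), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  train_ps <- pattern_stream(train_duration_s * 1000,
                             n_channels = n_channels,
                             n_patterns = n_patterns,
                             pattern_len_ms = pattern_len_ms)
  net <- wta_network_from_input(K, train_ps$train, kernel = kernel,
                                offset_c = plasticity$offset_c)
  inh <- inhibition_config(target_output_rate_hz = target_rate_hz,
                           reset_amplitude = 0)
  run <- run_simulation(train_ps$train, net, sim_config(dt = 1),
                        plasticity = plasticity, inhibition = inh,
                        kernel = kernel)
  test_ps <- pattern_stream(test_duration_s * 1000,
                            n_channels = n_channels,
                            frozen = train_ps$frozen,
                            pattern_len_ms = pattern_len_ms)
  test <- run_simulation(test_ps$train, run$network, sim_config(dt = 1),
                         plasticity = NULL, inhibition = inh,
                         kernel = kernel)
  spk_pat <- interval_pattern(test$output$time, test_ps$intervals)
  frac <- matrix(0, K, n_patterns + 1L)  # col 1 = noise
  for (k in seq_len(K)) {
    sel <- test$output$channel == k
    if (!any(sel)) next
    frac[k, ] <- tabulate(spk_pat[sel] + 1L,
                          nbins = n_patterns + 1L) / sum(sel)
  }
  claimed <- apply(frac[, -1L, drop = FALSE], 1, function(f) {
    if (max(f) >= spec_frac) which.max(f) else NA_integer_
  })
  unique_claim <- !is.na(claimed) &
    vapply(claimed, function(p) {
      !is.na(p) && sum(claimed == p, na.rm = TRUE) == 1L
    }, logical(1))
  noise_k <- which(is.na(claimed))
  structure(
    list(n_specialized = sum(unique_claim), claimed = claimed,
         spike_fractions = frac,
         noise_neuron_fraction =
           if (length(noise_k)) max(frac[noise_k, 1L]) else NA_real_,
         network = run$network, diagnostics = run$diagnostics,
         test_diagnostics = test$diagnostics),
    class = "example4_report"
  )
}

# pattern id (0 = noise) of the interval containing each time
interval_pattern <- function(times, intervals) {
  idx <- findInterval(times, intervals$start)
  idx[idx == 0L] <- 1L
  ifelse(times <= intervals$end[idx], intervals$pattern[idx], 0L)
}

#' STDP pairing-protocol curve
#'
#' Repeated pre/post spike pairs at a fixed stimulation frequency: pre
#' spikes at `j * T`, post spikes at `j * T + delta_t` (`T = 1000 / freq`).
#' At each post spike the continuous-time rule is evaluated with the
#' weight and learning rate held fixed, isolating the timing dependence.
#' The reported update per `delta_t` is the average over the pairings
#' after a transient (so EPSP overlap from earlier pairs has reached its
#' steady state).
#'
#' @param freq_hz Stimulation frequency (Hz).
#' @param delta_t Vector of time differences post - pre (ms).
#' @param w_fixed Fixed weight during the protocol. The default
#'   `log(0.2)` probes a synapse whose learned probability is mid-range.
#' @param eta Fixed learning rate.
#' @param c Offset constant.
#' @param kernel EPSP kernel.
#' @param n_pairings Number of pre/post pairs.
#' @param skip Pairings discarded as transient.
#' @return Data frame with columns `delta_t` and `update`.
#' @export
stdp_pairing_curve <- function(freq_hz, delta_t, w_fixed = log(0.2),
                               eta = 0.01, c = 1,
                               kernel = kernel_spec("alpha"),
                               n_pairings = 20L, skip = 10L) {
  T_ms <- 1000 / freq_hz
  upd <- vapply(delta_t, function(dt_) {
    pre <- (seq_len(n_pairings) - 1L) * T_ms
    post <- pre + dt_
    post <- post[post > 0]
    y <- alpha_trace(pre, post, kernel)
    use <- seq_along(post) > skip
    mean(complex_stdp_delta(w_fixed, y[use], eta, c))
  }, numeric(1))
  data.frame(delta_t = delta_t, update = upd)
}

#' Burst-pairing protocol
#'
#' Pre- and postsynaptic bursts (`n_pre` and `n_post` spikes at
#' `burst_hz`), with the post burst onset shifted by each entry of
#' `onset_delays` relative to the pre burst onset. Reports the cumulative
#' weight update over the post burst at fixed weight and learning rate.
#'
#' @param onset_delays Post-minus-pre burst onset differences (ms).
#' @param burst_hz Intra-burst spike rate (Hz).
#' @param n_pre,n_post Spikes per burst.
#' @inheritParams stdp_pairing_curve
#' @return Data frame with columns `onset_delay` and `total_update`.
#' @export
burst_protocol <- function(onset_delays = c(-120, -60, 10, 20, 30, 80,
                                            140),
                           burst_hz = 50, n_pre = 5L, n_post = 4L,
                           w_fixed = log(0.2), eta = 0.01, c = 1,
                           kernel = kernel_spec("alpha")) {
  isi <- 1000 / burst_hz
  pre <- (seq_len(n_pre) - 1L) * isi
  tot <- vapply(onset_delays, function(d) {
    post <- d + (seq_len(n_post) - 1L) * isi
    y <- alpha_trace(pre, post, kernel)
    sum(complex_stdp_delta(w_fixed, y, eta, c))
  }, numeric(1))
  data.frame(onset_delay = onset_delays, total_update = tot)
}

#' Frequency-dependent STDP curves and burst protocol
#'
#' Runs the pairing protocol at 1, 20 and 40 Hz over a `delta_t` grid
#' (restricted per frequency to avoid overlapping pairs) plus the
#' 50 Hz burst protocol, and summarizes the qualitative shape: at 1 Hz
#' the isolated complex-rule curve (EPSP-shaped LTP, flat LTD), at 20 Hz
#' timing-dependent LTD from overlapping EPSPs, at 40 Hz LTP throughout.
#'
#' @param freqs Stimulation frequencies (Hz).
#' @param max_dt Largest |delta_t| probed (ms); per frequency the grid is
#'   clipped to just under half the stimulation period.
#' @param dt_step Grid step (ms).
#' @inheritParams stdp_pairing_curve
#' @return List of class `stdp_curves_report` with one data frame per
#'   frequency, the burst table, and qualitative summaries.
#' @export
run_stdp_curves <- function(freqs = c(1, 20, 40), max_dt = 100,
                            dt_step = 1, w_fixed = log(0.2), eta = 0.01,
                            c = 1, kernel = kernel_spec("alpha")) {
  curves <- lapply(freqs, function(f) {
    lim <- min(max_dt, 0.48 * 1000 / f)
    grid <- seq(-lim, lim, by = dt_step)
    grid <- grid[abs(grid) > 1e-9]
    stdp_pairing_curve(f, grid, w_fixed, eta, c, kernel)
  })
  names(curves) <- paste0(freqs, "Hz")
  structure(
    list(curves = curves, freqs = freqs,
         burst = burst_protocol(w_fixed = w_fixed, eta = eta, c = c,
                                kernel = kernel),
         w_fixed = w_fixed, eta = eta),
    class = "stdp_curves_report"
  )
}
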