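# direct stochastic iteration of an update rule; independent of the
# simulation loop
iterate_rule <- function(n, w0, delta_fn) {
  w <- w0
  trail <- numeric(n)
  for (i in seq_len(n)) {
    w <- w + delta_fn(w)
    trail[i] <- w
  }
  trail
}

test_that("simple STDP deltas match the rule's closed form", {
  expect_equal(simple_stdp_delta(0, 1, eta = 0.1, c = 1), 0)
  expect_equal(simple_stdp_delta(2.3, 0, eta = 0.1), -0.1)
  expect_equal(simple_stdp_delta(log(0.5), 1, eta = 0.01, c = 1),
               0.01 * (2 - 1))
})

test_that("simple STDP converges to the log pre-activity probability", {
  set.seed(21)
  for (p in c(0.25, 0.75)) {
    trail <- iterate_rule(50000, 0, function(w) {
      simple_stdp_delta(w, rbinom(1, 1, p), eta = 0.002, c = 1)
    })
    w_hat <- mean(trail[40001:50000])
    expect_lt(abs(w_hat - log(p)), 0.05)
  }
})

test_that("complex STDP reduces to the simple rule on binary traces and finds ln(c E[y])", {
  expect_equal(complex_stdp_delta(1.2, 0, eta = 0.05), -0.05)
  w <- runif(5, -2, 0)
  expect_equal(complex_stdp_delta(w, 1, eta = 0.01, c = 2),
               simple_stdp_delta(w, 1, eta = 0.01, c = 2))
  # graded stationary traces: equilibrium at log(c * E[y])
  set.seed(22)
  trail <- iterate_rule(50000, -1, function(w) {
    complex_stdp_delta(w, runif(1, 0, 1.4), eta = 0.002, c = 1)
  })
  expect_lt(abs(mean(trail[40001:50000]) - log(0.7)), 0.05)
})

test_that("intrinsic plasticity drives b to the log win fraction", {
  expect_equal(intrinsic_delta(0, TRUE, 0.1), 0)
  expect_equal(intrinsic_delta(-1, FALSE, 0.1), -0.1)
  set.seed(23)
  trail <- iterate_rule(50000, log(1 / 3), function(b) {
    intrinsic_delta(b, runif(1) < 0.4, eta = 0.002)
  })
  expect_lt(abs(mean(trail[40001:50000]) - log(0.4)), 0.05)
})

test_that("timing-dependent LTD equilibrates at the before/after log-ratio", {
  # stationary uncorrelated before/after statistics: equilibrium 0
  expect_equal(ltd_variant_apply(0, 1, 1, eta = 0.01), 0)
  # pre only before post: always potentiates until e^{-w} caps it
  expect_gt(ltd_variant_apply(5, 1, 0, eta = 0.01), 0)
  expect_lt(ltd_variant_apply(5, 1, 0, eta = 0.01),
            ltd_variant_apply(0, 1, 0, eta = 0.01))
  set.seed(24)
  trail <- iterate_rule(60000, 0, function(w) {
    ltd_variant_apply(w, rbinom(1, 1, 0.6), rbinom(1, 1, 0.3),
                      eta = 0.002)
  })
  expect_lt(abs(mean(trail[50001:60000]) - log(2)), 0.05)
})

test_that("variance-tracking rate follows the stated formula and clips", {
  trk <- list(S = log(0.5), Q = log(0.5)^2)
  expect_equal(variance_tracking_rate(trk, eta_min = 1e-4, eta_max = 0.05),
               1e-4)  # zero variance
  trk$Q <- trk$S^2 + 0.01
  expect_equal(variance_tracking_rate(trk, eta_min = 1e-4, eta_max = 0.05),
               0.01 * 0.5 / 0.5)
  bad <- list(S = 0.5, Q = 0.5^2 + 0.01)
  expect_warning(eta <- variance_tracking_rate(bad), "eta_min")
  expect_equal(eta, 1e-4)
})

test_that("variance tracking approximates a 1/N learning-rate schedule", {
  set.seed(25)
  p <- 0.3
  w <- log(p)
  trk <- moment_tracker(w, spread = 0.05)
  n <- 20000
  etas <- numeric(n)
  for (i in seq_len(n)) {
    eta <- variance_tracking_rate(trk, eta_min = 1e-6, eta_max = 0.1,
                                  warn = FALSE)
    w <- w + simple_stdp_delta(w, rbinom(1, 1, p), eta = eta)
    trk <- list(S = (1 - eta) * trk$S + eta * w,
                Q = (1 - eta) * trk$Q + eta * w^2)
    etas[i] <- eta
  }
  idx <- seq(2000, n, by = 50)
  fit <- stats::lm(log(etas[idx]) ~ log(idx))
  expect_lt(abs(unname(stats::coef(fit)[2]) + 1), 0.2)
})

test_that("training with a weight offset c shifts weights by log(c) and preserves posteriors", {
  set.seed(26)
  code <- population_code(rep(3, 4))
  model <- random_mixture_model(2, rep(3, 4), concentration = 0.4)
  samp <- sample_evidence(model, 600)
  stream <- encode_stream(samp$data, code, active_rate_hz = 100,
                          pattern_ms = 40, gap_ms = 40)
  kern <- kernel_spec("rectangular_renewable", sigma = 40)
  inh <- inhibition_config(target_output_rate_hz = 100)
  out <- lapply(c(1, exp(5)), function(cc) {
    set.seed(99)
    W0 <- matrix(runif(2 * code$n_channels, -3, -0.5), 2) + log(cc)
    net <- wta_network(2, code$n_channels, offset_c = cc, weights = W0,
                       excitabilities = rep(log(0.5), 2))
    run <- run_simulation(stream, net, sim_config(dt = 1, seed = 123),
                          plasticity = plasticity_config(
                            "complex", eta = 0.01, offset_c = cc),
                          inhibition = inh, kernel = kern)
    run$network
  })
  dw <- out[[2]]$weights - out[[1]]$weights
  expect_equal(max(abs(dw - 5)), 0, tolerance = 0.05)
  m1 <- weights_to_model(out[[1]], code)
  m2 <- weights_to_model(out[[2]], code)
  post_diff <- vapply(seq_len(200), function(i) {
    max(abs(posterior(m1, samp$data[i, ]) - posterior(m2, samp$data[i, ])))
  }, numeric(1))
  expect_lt(max(post_diff), 1e-6)
})
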