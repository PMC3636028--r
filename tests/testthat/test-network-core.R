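test_that("membrane potential is the weighted trace sum plus bias minus inhibition", {
  net <- wta_network(2, 2, weights = matrix(0, 2, 2),
                     excitabilities = c(0, 0))
  expect_equal(membrane_potential(net, 1, c(0, 0)), 0)

  net2 <- wta_network(1, 2, weights = matrix(log(0.5), 1, 2),
                      excitabilities = log(0.25))
  expect_equal(membrane_potential(net2, 1, c(1, 1)), log(1 / 16),
               tolerance = 1e-12)
  expect_error(membrane_potential(net2, 3, c(1, 1)), "invalid")

  # independent dot-product oracle on random state
  set.seed(3)
  net3 <- wta_network(4, 30)
  y <- runif(30); I <- rnorm(1)
  for (k in 1:4) {
    oracle <- sum(vapply(seq_len(30), function(i) {
      net3$weights[k, i] * y[i]
    }, numeric(1))) + net3$excitabilities[k] - I
    expect_equal(membrane_potential(net3, k, y, I), oracle,
                 tolerance = 1e-12)
  }
})

test_that("relative firing probabilities are a shift-invariant softmax", {
  expect_equal(relative_firing_probabilities(c(0, 0, 0)), rep(1 / 3, 3))
  expect_equal(relative_firing_probabilities(log(c(1, 3))), c(0.25, 0.75))
  u <- c(-2, 0.5, 3, 1)
  expect_equal(relative_firing_probabilities(u),
               relative_firing_probabilities(u + 123.4),
               tolerance = 1e-12)
  expect_equal(sum(relative_firing_probabilities(rnorm(7))), 1)
  expect_error(relative_firing_probabilities(numeric()), "empty")
})

test_that("very negative potentials produce no spikes", {
  net <- wta_network(3, 1, weights = matrix(0, 3, 1),
                     excitabilities = rep(-200, 3))
  set.seed(1)
  spikes <- replicate(2000, length(wta_step(net, traces = 0)))
  expect_equal(sum(spikes), 0)
})

test_that("rate convention: exp(u) = 1 gives r0 Hz", {
  # constant u = 0 via zero weights/biases, no inhibition components
  net <- wta_network(2, 1, weights = matrix(0, 2, 1),
                     excitabilities = c(0, 0))
  empty <- spike_train(n_channels = 1, duration = 100e3)
  inh <- inhibition_config(balance = "none", reset_amplitude = 0)
  run <- run_simulation(empty, net, sim_config(dt = 0.1, seed = 5),
                        inhibition = inh)
  # each neuron: Poisson(100) expected spikes over 100 s at 1 Hz
  for (k in 1:2) {
    n_k <- sum(run$output$channel == k)
    expect_lt(abs(n_k - 100), 3 * sqrt(100))
  }
})

test_that("winner identities follow the softmax of the membrane potentials", {
  set.seed(7)
  K <- 4
  b <- c(1.2, 0.1, -0.5, 0.8)
  net <- wta_network(K, 1, weights = matrix(0, K, 1), excitabilities = b)
  empty <- spike_train(n_channels = 1, duration = 40e3)
  inh <- inhibition_config(balance = "exact", target_output_rate_hz = 150,
                           reset_amplitude = 0)
  run <- run_simulation(empty, net, sim_config(dt = 1), inhibition = inh)
  counts <- tabulate(run$output$channel, K)
  expect_gt(sum(counts), 3000)
  p <- relative_firing_probabilities(b)
  expect_gt(stats::chisq.test(counts, p = p)$p.value, 0.01)
})

test_that("independent-Poisson and rate-rescaled modes agree on winner identity", {
  set.seed(8)
  K <- 3
  b <- c(0.5, -0.3, 0.9)
  net <- wta_network(K, 1, weights = matrix(0, K, 1), excitabilities = b)
  empty <- spike_train(n_channels = 1, duration = 30e3)
  inh <- inhibition_config(target_output_rate_hz = 150,
                           reset_amplitude = 0)
  hist_mode <- function(mode) {
    run <- run_simulation(empty, net,
                          sim_config(dt = 1, firing_mode = mode),
                          inhibition = inh)
    tabulate(run$output$channel, K) / n_spikes(run$output)
  }
  h1 <- hist_mode("independent_poisson")
  h2 <- hist_mode("rate_rescaled_sampling")
  expect_lt(sum(abs(h1 - h2)) / 2, 0.03)  # total variation
})

test_that("a common inhibition signal changes the rate but not the winners", {
  set.seed(9)
  K <- 3
  b <- c(3.2, 4.1, 2.6)
  net <- wta_network(K, 1, weights = matrix(0, K, 1), excitabilities = b)
  empty <- spike_train(n_channels = 1, duration = 150e3)
  base <- inhibition_config(balance = "none", reset_amplitude = 0,
                            ou_sigma = 1e-12, ou_mu = 0)
  shifted <- inhibition_config(balance = "none", reset_amplitude = 0,
                               ou_sigma = 1e-12, ou_mu = 1)
  r1 <- run_simulation(empty, net, sim_config(dt = 0.5), inhibition = base)
  r2 <- run_simulation(empty, net, sim_config(dt = 0.5),
                       inhibition = shifted)
  # rates differ by roughly exp(-1)
  expect_lt(abs(n_spikes(r2$output) / n_spikes(r1$output) - exp(-1)), 0.1)
  h1 <- tabulate(r1$output$channel, K) / n_spikes(r1$output)
  h2 <- tabulate(r2$output$channel, K) / n_spikes(r2$output)
  expect_lt(sum(abs(h1 - h2)) / 2, 0.03)
})

test_that("simulation contracts: zero duration, frozen weights, determinism", {
  set.seed(10)
  train <- poisson_train(20, 2000, 12)
  net <- wta_network(3, 12)
  zero <- run_simulation(train, net, sim_config(dt = 1, duration = 0))
  expect_equal(n_spikes(zero$output), 0L)
  expect_identical(zero$network$weights, net$weights)

  frozen <- run_simulation(train, net, sim_config(dt = 1, seed = 42))
  expect_identical(frozen$network$weights, net$weights)
  expect_identical(frozen$network$excitabilities, net$excitabilities)

  again <- run_simulation(train, net, sim_config(dt = 1, seed = 42))
  expect_identical(frozen$output$time, again$output$time)
  expect_identical(frozen$output$channel, again$output$channel)

  bad <- wta_network(3, 5)
  expect_error(run_simulation(train, bad), "channel count")
})
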