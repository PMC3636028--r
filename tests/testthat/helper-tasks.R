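# Shared fixtures for the heavier learning tests.

# A separated 3-cause, 5-group mixture task: evidence data plus an
# encoded spike stream whose gap equals the integration window, so every
# plasticity update sees evidence from a single pattern.
make_sem_vs_em_task <- function(seed, n_train = 8000, n_test = 500,
                                active_rate_hz = 100, sigma = 40) {
  set.seed(seed)
  model <- random_mixture_model(3, rep(4, 5), concentration = 0.3)
  code <- population_code(rep(4, 5))
  samp <- sample_evidence(model, n_train + n_test)
  stream <- encode_stream(samp$data[seq_len(n_train), ], code,
                          active_rate_hz = active_rate_hz,
                          pattern_ms = sigma, gap_ms = sigma)
  list(model = model, code = code,
       train = samp$data[seq_len(n_train), ],
       test = samp$data[n_train + seq_len(n_test), ],
       labels_test = samp$labels[n_train + seq_len(n_test)],
       stream = stream, sigma = sigma)
}

# Train a WTA circuit on the task stream and return the extracted model.
train_sem_on_task <- function(task, K = 3, eta_b = 0.001) {
  net <- wta_network(K, task$code$n_channels)
  run <- run_simulation(
    task$stream, net, sim_config(dt = 1),
    plasticity = plasticity_config("complex", eta_b = eta_b,
                                   eta_max = 0.1),
    inhibition = inhibition_config(target_output_rate_hz = 100),
    kernel = kernel_spec("rectangular_renewable", sigma = task$sigma))
  list(run = run, model = weights_to_model(run$network, task$code))
}
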