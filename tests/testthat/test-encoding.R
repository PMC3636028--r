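test_that("population code partitions channels with one channel per (group, value)", {
  code <- population_code(c(2, 3, 4))
  expect_equal(code$n_channels, 9L)
  expect_equal(code$group_of, rep(1:3, c(2, 3, 4)))
  expect_equal(channel_for(code, 2, 3), 5L)
  expect_equal(group_channels(code, 3), 6:9)
  expect_error(channel_for(code, 1, 3), "out of range")
  # every (group, value) pair maps to a distinct channel
  all_ch <- unlist(lapply(1:3, function(j) group_channels(code, j)))
  expect_equal(sort(all_ch), 1:9)
  expect_error(evidence_vector(c(3, 1, 1), code), "out of range")
})

test_that("encode_stream fires the active channel at the requested Poisson rate", {
  code <- population_code(3)
  set.seed(41)
  empty <- encode_stream(matrix(1L, 5, 1), code, active_rate_hz = 0,
                         pattern_ms = 100, gap_ms = 0)
  expect_equal(n_spikes(empty), 0L)

  one <- encode_stream(matrix(2L, 1, 1), code, active_rate_hz = 20,
                       pattern_ms = 1000, gap_ms = 0)
  expect_true(all(one$channel == 2L))
  expect_lt(abs(n_spikes(one) - 20), 3 * sqrt(20))

  # inactive channels stay silent; missing groups stay silent
  code2 <- population_code(c(2, 2))
  st <- encode_stream(matrix(c(1L, NA), 1), code2, active_rate_hz = 200,
                      pattern_ms = 500, gap_ms = 0)
  expect_true(all(st$channel == 1L))
})

test_that("oscillatory rate modulation preserves the mean rate within 2%", {
  code <- population_code(1)
  set.seed(42)
  n_pat <- 2000  # 2000 x 50 ms = 100 s
  st <- encode_stream(matrix(1L, n_pat, 1), code, active_rate_hz = 100,
                      pattern_ms = 50, gap_ms = 0,
                      osc_amplitude = 0.5, osc_freq_hz = 20)
  rate <- 1000 * n_spikes(st) / train_duration(st)
  expect_lt(abs(rate / 100 - 1), 0.02)
  expect_error(encode_stream(matrix(1L, 1, 1), code, osc_amplitude = 1.5),
               "negative rates")
})

test_that("the oscillation actually modulates spike timing", {
  code <- population_code(1)
  set.seed(43)
  st <- encode_stream(matrix(1L, 400, 1), code, active_rate_hz = 60,
                      pattern_ms = 50, gap_ms = 0,
                      osc_amplitude = 0.8, osc_freq_hz = 20)
  phase <- (st$time %% 50) / 50 * 2 * pi
  # spikes should concentrate at the sine peak (phase pi/2)
  conc <- mean(sin(phase))
  expect_gt(conc, 0.3)  # 0.8 amplitude -> E[sin] = A/2 = 0.4
})

test_that("decode_evidence inverts the encoder and flags silent groups", {
  code <- population_code(c(2, 3))
  silent <- spike_train(n_channels = code$n_channels, duration = 100)
  expect_equal(decode_evidence(silent, 50, code, 40),
               rep(NA_integer_, 2))
  one <- spike_train(30, channel_for(code, 1, 2), n_channels = 5)
  expect_equal(decode_evidence(one, 40, code, 40), c(2L, NA))
  # most recent spike wins within a group
  two <- spike_train(c(10, 20), c(1L, 2L), n_channels = 5)
  expect_equal(decode_evidence(two, 30, code, 40)[1], 2L)

  set.seed(44)
  patterns <- cbind(sample(1:2, 30, TRUE), sample(1:3, 30, TRUE))
  st <- encode_stream(patterns, code, active_rate_hz = 300,
                      pattern_ms = 40, gap_ms = 10)
  hits <- 0; tot <- 0
  for (i in 1:30) {
    ev <- decode_evidence(st, (i - 1) * 50 + 40, code, 40)
    obs <- !is.na(ev)
    hits <- hits + sum(ev[obs] == patterns[i, obs])
    tot <- tot + sum(obs)
  }
  expect_equal(hits, tot)  # every observed group decodes to the original
  expect_gt(tot, 50)       # at 300 Hz almost nothing is missing
})

test_that("each group's total input rate does not depend on the encoded value", {
  code <- population_code(c(4, 4))
  set.seed(45)
  rates <- sapply(1:4, function(v) {
    st <- encode_stream(matrix(c(v, v), 50, 2, byrow = TRUE), code,
                        active_rate_hz = 80, pattern_ms = 50, gap_ms = 0)
    1000 * n_spikes(st) / train_duration(st) / 2
  })
  expect_true(all(abs(rates - 80) < 3 * sqrt(80 * 2.5) / 2.5))
})

test_that("missing-rate estimation tracks the analytic missing probability", {
  code <- population_code(rep(2, 20))
  set.seed(46)
  patterns <- matrix(sample(1:2, 100 * 20, TRUE), 100, 20)
  st <- encode_stream(patterns, code, active_rate_hz = 25,
                      pattern_ms = 40, gap_ms = 0)
  est <- estimate_missing_rate(st, code, sigma = 40)
  expect_lt(abs(est - exp(-25 * 0.04)), 0.05)
})
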