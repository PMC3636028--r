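test_that("gaussian blob dataset follows its priors and pixel statistics", {
  set.seed(51)
  ds <- gaussian_blob_dataset(5000)
  freq <- tabulate(ds$labels, 4) / 5000
  pri <- c(0.1, 0.2, 0.3, 0.4)
  for (k in 1:4) {
    expect_lt(abs(freq[k] - pri[k]), 3 * sqrt(pri[k] * (1 - pri[k]) / 5000))
  }
  expect_true(all(ds$images %in% c(0L, 1L)))
  # the center pixel of cause k is on most often under label k
  for (k in 1:4) {
    cen <- ds$centers[k, 1] + (ds$centers[k, 2] - 1) * ds$grid
    pos <- which(ds$permutation == cen)
    expect_length(pos, 1)  # blob centers survive the activity pruning
    on_rate <- vapply(1:4, function(l) {
      mean(ds$images[ds$labels == l, pos])
    }, numeric(1))
    expect_equal(which.max(on_rate), k)
  }
  # single-cause generation
  ds1 <- gaussian_blob_dataset(50, priors = c(1, 0, 0, 0))
  expect_true(all(ds1$labels == 1L))
})

test_that("oriented bars have the right geometry, symmetry and noise", {
  img0 <- oriented_bar_image(0, flip_prob = 0)
  # horizontal band of exactly 7 rows through the center, inside the mask
  on_rows <- which(colSums(img0) > 0)
  expect_equal(on_rows, 11:17)
  cx <- 14
  for (r in 11:17) {
    cols <- which(img0[, r] == 1L)
    inside <- which((seq_len(28) - cx)^2 + (r - cx)^2 <= 14^2)
    expect_equal(cols, inside)
  }
  # theta and theta + 180 give the same bar
  expect_identical(oriented_bar_image(37.3, flip_prob = 0),
                   oriented_bar_image(217.3, flip_prob = 0))
  # flip_prob = 0.5: masked area is on about half the time, any angle
  set.seed(52)
  xy <- expand.grid(x = 1:28, y = 1:28)
  mask <- (xy$x - 14)^2 + (xy$y - 14)^2 <= 14^2
  for (a in c(10, 95)) {
    img <- oriented_bar_image(a, flip_prob = 0.5)
    frac <- mean(as.vector(img)[mask])
    expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / sum(mask)))
  }
})

test_that("pattern streams replay frozen patterns in rate-stationary noise", {
  set.seed(53)
  ps <- pattern_stream(30e3, n_channels = 100)
  iv <- ps$intervals
  expect_true(all(diff(iv$start) > 0))
  expect_true(all(iv$end[-nrow(iv)] <= iv$start[-1] + 1e-9))
  # every presentation of a pattern contains its frozen spikes exactly
  for (r in which(iv$pattern > 0)[1:10]) {
    fz <- ps$frozen[[iv$pattern[r]]]
    seg <- ps$train[ps$train$time >= iv$start[r] &
                      ps$train$time < iv$end[r], ]
    for (j in seq_along(fz$time)) {
      expect_true(any(abs(seg$time - (iv$start[r] + fz$time[j])) < 1e-9 &
                        seg$channel == fz$channel[j]))
    }
  }
  # rate stationarity: in-pattern rate (15 + 5) matches gap rate (20)
  pat_dur <- sum(iv$end[iv$pattern > 0] - iv$start[iv$pattern > 0])
  gap_dur <- sum(iv$end[iv$pattern == 0] - iv$start[iv$pattern == 0])
  spk_pat <- semwta:::interval_pattern(ps$train$time, iv)
  r_pat <- sum(spk_pat > 0) / (100 * pat_dur / 1000)
  r_gap <- sum(spk_pat == 0) / (100 * gap_dur / 1000)
  expect_lt(abs(r_pat - 20), 3 * sqrt(20 / (100 * pat_dur / 1000)))
  expect_lt(abs(r_gap - 20), 3 * sqrt(20 / (100 * gap_dur / 1000)))
  # total spike count
  tot_exp <- 100 * 20 * train_duration(ps$train) / 1000
  expect_lt(abs(n_spikes(ps$train) - tot_exp), 3 * sqrt(tot_exp))
  # reproducibility by seed, and frozen replay into a fresh stream
  set.seed(53)
  ps2 <- pattern_stream(30e3, n_channels = 100)
  expect_identical(ps$train$time, ps2$train$time)
  ps3 <- pattern_stream(10e3, n_channels = 100, frozen = ps$frozen)
  expect_identical(ps3$frozen, ps$frozen)
})
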