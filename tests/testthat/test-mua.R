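small_layout <- electrode_layout(n_x = 2, n_y = 2)

test_that("synthetic recordings are seeded and dimensionally sound", {
  spec <- synth_ephys_spec(seed = 5)
  a <- synth_mua(spec, electrode_layout(), n_trials = 2)
  b <- synth_mua(spec, electrode_layout(), n_trials = 2)
  expect_identical(a$samples, b$samples)
  expect_equal(dim(a$samples), c(56, 2 * 12000))
  expect_equal(a$onsets, c(1, 12001))
  expect_error(synth_mua(synth_ephys_spec(active_mask = c(TRUE, FALSE)),
                         electrode_layout()), "active_mask")
})

test_that("zero-burst recordings give statistically flat channel amplitudes", {
  lay <- electrode_layout(n_x = 2, n_y = 3)
  spec <- synth_ephys_spec(burst_uv = 0, noise_uv = 5, seed = 6)
  amps <- attr(mua_amplitude(synth_mua(spec, lay, n_trials = 4)), "mean")
  expect_lt(diff(range(amps)) / mean(amps), 0.5)
})

test_that("the MUA chain rejects out-of-band input and passes burst energy", {
  lay <- small_layout
  spec <- synth_ephys_spec(burst_uv = 40, noise_uv = 0, seed = 7,
                           active_mask = c(TRUE, FALSE, FALSE, FALSE))
  rec <- synth_mua(spec, lay, n_trials = 1)
  # replace channel 2 with a pure 60 Hz sinusoid (outside 500-7000 Hz)
  t <- seq_len(ncol(rec$samples)) / rec$fs
  rec$samples[2, ] <- 100 * sin(2 * pi * 60 * t)
  amps <- mua_amplitude(rec)
  expect_lt(amps[2, 1], 1)          # <= 1% of the 100 uV sinusoid
  expect_gt(amps[1, 1], 5)          # burst channel clearly responds
  expect_equal(mua_amplitude(structure(
    list(samples = matrix(0, 2, 9000), fs = 30000, onsets = 1L,
         layout = lay, trial_len = 9000), class = "mua_recording"))[1, 1], 0)
})

test_that("extracted amplitude tracks the analytic burst envelope", {
  lay <- small_layout
  fs <- 30000
  # tone carrier: the rectified envelope is deterministic, giving a clean
  # analytic oracle (|sqrt(2) cos| averages to 2 sqrt(2) / pi)
  spec <- synth_ephys_spec(burst_uv = 60, noise_uv = 0, seed = 8,
                           carrier = "tone",
                           active_mask = c(TRUE, rep(FALSE, 3)))
  rec <- synth_mua(spec, lay, n_trials = 5)
  amp <- attr(mua_amplitude(rec), "mean")[1]
  # oracle: the second filter applied to the analytic rectified envelope
  nb <- round(spec$burst_ms / 1000 * fs)
  env <- numeric(12000)
  lag <- round(spec$latency_ms / 1000 * fs)
  env[lag + seq_len(nb)] <- spec$burst_uv *
    0.5 * (1 - cos(2 * pi * seq_len(nb) / (nb + 1))) * (2 * sqrt(2) / pi)
  lp <- signal::butter(4, 200 / (fs / 2), type = "low")
  hp <- signal::butter(4, 10 / (fs / 2), type = "high")
  oracle <- max(signal::filtfilt(hp, signal::filtfilt(lp, env)))
  expect_lt(abs(amp - oracle) / oracle, 0.15)
})

test_that("pipeline amplitude is linear in the injected burst amplitude", {
  lay <- small_layout
  levels <- c(10, 20, 30, 40, 50)
  mean_amp <- vapply(levels, function(a) {
    per_seed <- vapply(1:20, function(s) {
      spec <- synth_ephys_spec(burst_uv = a, noise_uv = 2, seed = s,
                               active_mask = c(TRUE, rep(FALSE, 3)))
      rec <- synth_mua(spec, lay, n_trials = 1, trial_ms = 300)
      mua_amplitude(rec, window_ms = c(0, 150))[1, 1]
    }, numeric(1))
    mean(per_seed)
  }, numeric(1))
  fit <- stats::lm(mean_amp ~ levels)
  expect_gt(summary(fit)$r.squared, 0.95)
  # doubling the burst doubles the response within 10%
  expect_equal(mean_amp[4] / mean_amp[2], 2, tolerance = 0.1)
})

test_that("bad channels are zeroed idempotently", {
  lay <- electrode_layout(bad_channels = c(3, 17))
  a <- seq_len(56)
  z <- zero_bad_channels(a, lay)
  expect_equal(z[c(3, 17)], c(0, 0))
  expect_equal(z[-c(3, 17)], a[-c(3, 17)])
  expect_identical(zero_bad_channels(z, lay), z)
  expect_identical(zero_bad_channels(a, electrode_layout()), a)
  all_bad <- electrode_layout(bad_channels = 1:56)
  expect_true(all(zero_bad_channels(a, all_bad) == 0))
  expect_error(electrode_layout(bad_channels = 99), "range")
})

test_that("modified Akima interpolation matches an independent implementation", {
  # expected values computed once with an independent makima implementation
  y <- c(0, 0, 0, 1, 0, 0, 2, 5, 3, 0)
  xi <- c(1.25, 3.5, 4.25, 6.75, 7.5, 8.25, 9.9)
  expect_equal(makima(1:10, y, xi),
               c(0, 0.5, 0.871875, 1.38474265, 3.73161765, 4.87734375, 0.33555),
               tolerance = 1e-8)
  # node exactness and flat-region behaviour (no spurious wiggles)
  expect_equal(makima(1:10, y, 1:10), y, tolerance = 1e-12)
  expect_equal(makima(1:5, rep(2, 5), seq(1, 5, 0.1)), rep(2, 41))
})

test_that("activation maps refine the grid 4x and are exact at the nodes", {
  amps <- as.numeric(outer(sin(1:7), cos(1:8)))^2 * 10
  m <- map_sc_response(amps, electrode_layout())
  expect_equal(dim(m$image), c(4 * 6 + 1, 4 * 7 + 1))
  expect_equal(m$image[seq(1, 25, by = 4), seq(1, 29, by = 4)],
               m$channel_grid, tolerance = 1e-12)
  # constant in -> constant out
  cm <- map_sc_response(rep(3, 56), electrode_layout())
  expect_equal(range(cm$image), c(3, 3))
  # single hot channel: interpolated maximum at that channel's node
  hot <- rep(0, 56); hot[20] <- 5
  hm <- map_sc_response(hot, electrode_layout())
  pk <- arrayInd(which.max(hm$image), dim(hm$image))
  node <- arrayInd(20, c(7, 8))
  expect_equal(as.integer(pk), as.integer((node - 1) * 4 + 1))
  # bounded overshoot (Akima damping)
  expect_lt(max(hm$image), 1.5 * max(hot))
  expect_gt(min(hm$image), -1.5 * max(hot))
})

test_that("response similarity is maximal for a matching map and ordered", {
  amps <- as.numeric(letter_mask("C", 8)[1:7, 1:8]) * 10
  m <- map_sc_response(amps, electrode_layout())
  self <- response_similarity(m, matrix(amps, 7, 8))
  inv <- response_similarity(m, max(amps) - matrix(amps, 7, 8))
  expect_gt(self, 0.9)
  expect_gt(self, inv)
})

test_that("letter-masked bursts reproduce the mask in the activation map", {
  lay <- electrode_layout()
  mask <- letter_mask("C", 8)[1:7, 1:8] > 0
  spec <- synth_ephys_spec(burst_uv = 50, noise_uv = 5, seed = 12,
                           active_mask = as.vector(mask))
  rec <- synth_mua(spec, lay, n_trials = 3)
  amps <- attr(mua_amplitude(rec), "mean")
  est <- matrix(amps >= 0.5 * max(amps), 7, 8)
  jaccard <- sum(est & mask) / sum(est | mask)
  expect_gte(jaccard, 0.6)
})
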