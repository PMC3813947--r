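test_that("spiking duty cycle matches the worked arithmetic", {
  expect_equal(spiking_duty_cycle(5, 0.005), 0.025)
  expect_equal(spiking_duty_cycle(0, 1), 0)
  expect_equal(spiking_duty_cycle(300, 0.005), 1)
})

test_that("median-based noise estimate recovers sigma and resists spikes", {
  rec0 <- recording(rep(0, 2000), 10000)
  expect_equal(estimate_noise_sigma(rec0)$sigma_n, 0)
  expect_error(detect_spikes(rec0, estimate_noise_sigma(rec0)), "zero")

  set.seed(21)
  x <- rnorm(2e5, 0, 2)
  nz <- estimate_noise_sigma(recording(x, 10000))
  expect_equal(nz$sigma_n, 2, tolerance = 0.02)
  expect_identical(nz$threshold, 5 * nz$sigma_n)

  # 10-sigma spikes at 5 Hz, 5-ms width (duty cycle 0.025) barely move it
  spiky <- x
  starts <- seq(1000, 2e5 - 100, by = 2000)  # 5 Hz at 10 kHz
  for (s in starts) spiky[s:(s + 49)] <- spiky[s:(s + 49)] + 20
  nz_s <- estimate_noise_sigma(recording(spiky, 10000))
  expect_lt(abs(nz_s$sigma_n - nz$sigma_n) / nz$sigma_n, 0.05)

  expect_error(estimate_noise_sigma(recording(rnorm(100), 100)), "1000")
})

test_that("noise estimate is stable across halves and scales linearly", {
  set.seed(22)
  x <- rnorm(4e5, 0, 3)
  s1 <- estimate_noise_sigma(recording(x[1:2e5], 10000))$sigma_n
  s2 <- estimate_noise_sigma(recording(x[2e5 + 1:2e5], 10000))$sigma_n
  expect_lt(abs(s1 - s2) / s1, 0.02)

  rec <- recording(x, 10000)
  nz <- estimate_noise_sigma(rec)
  nz2 <- estimate_noise_sigma(recording(2 * x, 10000))
  expect_equal(nz2$sigma_n, 2 * nz$sigma_n)
  ev <- detect_spikes(rec, nz)
  ev2 <- detect_spikes(recording(2 * x, 10000), nz2)
  expect_equal(ev2$peak_index, ev$peak_index)
  expect_equal(ev2$amplitude, 2 * ev$amplitude)
  expect_equal(ev2$snr, ev$snr)
})

test_that("threshold detection finds constructed pulses at their peaks", {
  set.seed(23)
  x <- rnorm(10000, 0, 1)
  pulse <- 8 * exp(-0.5 * ((-20:20) / 4)^2)
  x[4981:5021] <- x[4981:5021] + pulse
  rec <- recording(x, 10000)
  nz <- noise_obj(1)
  ev <- detect_spikes(rec, nz)
  expect_equal(nrow(ev), 1)
  expect_lte(abs(ev$peak_index - 5001), 1)
  expect_gt(ev$amplitude, nz$threshold)
  expect_equal(ev$snr, ev$amplitude / nz$sigma_n)

  # zero signal with an injected (nonzero) noise estimate: nothing detected
  ev0 <- detect_spikes(recording(rep(0, 2000), 10000), nz)
  expect_equal(nrow(ev0), 0)

  # two peaks 0.5 ms apart: only the larger kept at 1-ms dead time
  y <- rep(0, 5000)
  y[1000] <- 10; y[1005] <- 7
  evm <- detect_spikes(recording(y, 10000), nz, min_separation = 0.001)
  expect_equal(evm$peak_index, 1000L)
})

test_that("detection recovers generator ground truth at high SNR", {
  specs <- template_specs(group_id = 1, peak_snr = 8, n_spikes = 200,
                          rise_ms = 0.25, fall_ms = 0.4, ahp_frac = 0.3,
                          ahp_tau_ms = 4)
  ds <- generate_dataset(specs, epoch_s = 60, noise_sigma = 10,
                         min_spacing_s = 0.03, seed = 24)
  nz <- estimate_noise_sigma(ds$recording)
  ev <- detect_spikes(ds$recording, nz, min_separation = 0.01)
  expect_equal(nrow(ev), 200)
  matched <- vapply(ds$ground_truth$time, function(t) {
    min(abs(ev$timestamp - t))
  }, numeric(1))
  expect_lte(max(matched), 0.0002)
})

test_that("waveform extraction is peak-aligned with edge-drop warnings", {
  x <- rep(0, 10000)
  x[5001] <- 50
  x[5000] <- 30; x[5002] <- 30
  rec <- recording(x, 10000)
  ev <- tibble::tibble(timestamp = 0.5, peak_index = 5001L)
  ws <- extract_waveforms(rec, ev)
  expect_equal(dim(ws$waveforms), c(1, 250))
  expect_equal(ws$align_index, 121L)
  expect_equal(which.max(ws$waveforms[1, ]), 121L)

  near_edge <- tibble::tibble(timestamp = c(0.005, 0.5),
                              peak_index = c(51L, 5001L))
  expect_warning(ws2 <- extract_waveforms(rec, near_edge), "dropped")
  expect_equal(nrow(ws2$waveforms), 1)
  expect_equal(ws2$kept, 2L)

  # rows equal template at inserted positions when noise is absent
  tpl <- unit_template()
  spec1 <- template_specs(group_id = 1, peak_snr = 6, n_spikes = 20,
                          rise_ms = 0.55, fall_ms = 0.55, ahp_frac = 0.45,
                          ahp_tau_ms = 6)
  zero_noise <- rep(0, 30 * 10000)
  ds <- generate_dataset(spec1, epoch_s = 30, noise_sigma = 10,
                         noise_samples = zero_noise, min_spacing_s = 0.05,
                         seed = 25)
  gt_idx <- round(ds$ground_truth$time * 10000) + 1L
  ws3 <- extract_waveforms(ds$recording,
                           tibble::tibble(timestamp = ds$ground_truth$time,
                                          peak_index = gt_idx))
  for (i in seq_len(nrow(ws3$waveforms))) {
    expect_equal(ws3$waveforms[i, ], 60 * tpl, tolerance = 1e-12)
  }
})

test_that("reference construction averages the selected snippets", {
  row <- c(rep(0, 120), 10, rep(0, 129))
  m <- matrix(rep(row, 20), nrow = 20, byrow = TRUE)
  ws <- ws_from_matrix(m)
  ref <- build_reference(ws, 1:20)
  expect_equal(ref$mean_waveform, row)
  expect_equal(ref$n_averaged, 20)

  m2 <- rbind(rep(0, 250), rep(2, 250))
  ref2 <- build_reference(ws_from_matrix(m2), 1:2)
  expect_equal(ref2$mean_waveform, rep(1, 250))

  expect_error(build_reference(ws, integer(0)), "empty")

  # CLT: mean of 20 template+noise rows within 3 sigma/sqrt(20) pointwise
  set.seed(29)
  tpl <- 60 * unit_template()
  noisy <- t(replicate(20, tpl + rnorm(250, 0, 10)))
  ref3 <- build_reference(ws_from_matrix(noisy), 1:20)
  expect_lt(max(abs(ref3$mean_waveform - tpl)), 3 * 10 / sqrt(20))
})
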