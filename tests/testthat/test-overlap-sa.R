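# A 60-s recording carrying template B (peak SNR 6 shape) at known times,
# used across the SA tests.
sa_fixture <- function(noise_sigma = 10, seed = 61, n_b = 30) {
  tplB <- unit_template(row = 4)
  times <- seq(1, by = 1.9, length.out = n_b)
  x <- if (noise_sigma > 0) {
    with_seed_local(seed, rnorm(60 * 10000, 0, noise_sigma))
  } else rep(0, 60 * 10000)
  ampB <- 6 * 10   # SNR 6 against sigma = 10 uV
  for (t in times) {
    p <- round(t * 10000) + 1L
    x[(p - 120):(p + 129)] <- x[(p - 120):(p + 129)] + ampB * tplB
  }
  list(rec = recording(x, 10000), times = times, tplB = ampB * tplB,
       sigma = 10)
}

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}

refA_fixture <- function() {
  ref_from_wave(4 * 10 * unit_template(row = 3))
}

test_that("residuals are exact pointwise differences with located maxima", {
  refA <- refA_fixture()
  res0 <- compute_residual(refA$mean_waveform, refA)
  expect_true(all(res0$full_residual == 0))
  expect_equal(res0$residual_peak, 0)

  # overlap construction: host + template B peaking 4 ms earlier
  fx <- sa_fixture(noise_sigma = 0)
  shift <- 40L   # 4 ms at 10 kHz
  addB <- c(fx$tplB[(shift + 1):250], rep(0, shift))  # B peak at sample 81
  outl <- refA$mean_waveform + addB
  res <- compute_residual(outl, refA)
  expect_equal(res$max_index, 121L - shift)
  expect_gte(res$max_time_ms, 2)
  expect_lt(res$max_time_ms, 15)
  expect_equal(length(res$segment), 50)
  expect_equal(res$segment, addB[(81 - 20):(81 + 29)])
  expect_equal(res$residual_peak, 60)

  # doubled amplitude: the residual is a copy of the reference
  res2 <- compute_residual(2 * refA$mean_waveform, refA)
  expect_equal(res2$full_residual, refA$mean_waveform)
  expect_equal(res2$max_index, 121L)
  expect_gt(cor(res2$segment,
                refA$mean_waveform[(121 - 20):(121 + 29)]), 0.999)

  expect_error(compute_residual(rep(0, 100), refA), "misaligned")
})

test_that("recording scan finds inserted templates and nothing else", {
  fx <- sa_fixture(noise_sigma = 0)
  refA <- refA_fixture()
  shift <- 40L
  addB <- c(fx$tplB[(shift + 1):250], rep(0, shift))
  res <- compute_residual(refA$mean_waveform + addB, refA)

  m <- scan_recording(res, fx$rec, epoch = 60)
  expect_gte(m$n_matches, length(fx$times))
  expect_true(all(m$matches$correlation > 0.999))
  # every insertion is matched at its true time
  hits <- vapply(fx$times, function(t) {
    min(abs(m$matches$match_time - t))
  }, numeric(1))
  expect_lt(max(hits), 0.001)
  expect_true(all(abs(1 - m$matches$magnitude_ratio) < 0.30))

  # all-zero recording: no matches
  m0 <- scan_recording(res, recording(rep(0, 1e5), 10000), epoch = 10)
  expect_equal(m0$n_matches, 0)

  # magnitude gate: candidates at 1.4x the residual peak are rejected
  rec_big <- recording(1.4 * fx$rec$samples, 10000)
  mb <- scan_recording(res, rec_big, epoch = 60)
  expect_equal(mb$n_matches, 0)

  # zero-variance residual: no scan
  res_flat <- res
  res_flat$segment <- rep(0, 50)
  res_flat$residual_peak <- 0
  expect_equal(scan_recording(res_flat, fx$rec)$n_matches, 0)
})

test_that("FFT sliding correlation agrees with the direct oracle", {
  set.seed(62)
  y <- rnorm(3000)
  y[1000:1049] <- y[1000:1049] + 5 * unit_template()[101:150]
  seg <- 5 * unit_template()[101:150] + rnorm(50, 0, 0.3)
  fast <- oligosort:::sliding_ncc(y, seg)
  slow <- ncc_oracle(y, seg)
  expect_equal(fast, slow, tolerance = 1e-9)
})

test_that("outlier classification follows the three verdict routes", {
  fx <- sa_fixture(noise_sigma = 10, seed = 63)
  refA <- refA_fixture()
  nz <- noise_obj(fx$sigma)

  # zero residual: retrieved as sub-threshold noise
  res0 <- compute_residual(refA$mean_waveform, refA)
  dec0 <- classify_outlier(res0, NULL, nz, refA)
  expect_equal(dec0$verdict, "retrieved-subthreshold")

  # full-amplitude residual present in the recording: retrieved by matching
  shift <- 40L
  addB <- c(fx$tplB[(shift + 1):250], rep(0, shift))
  res <- compute_residual(refA$mean_waveform + addB, refA)
  m <- scan_recording(res, fx$rec, epoch = 60)
  dec <- classify_outlier(res, m, nz, refA)
  expect_gt(res$residual_peak, 4 * nz$sigma_n)  # not sub-threshold
  expect_equal(dec$verdict, "retrieved-matched")
  expect_true(dec$retrieved)

  # double-amplitude outlier: flagged as the known pitfall, never retrieved,
  # even though its residual (a copy of the reference) may match recordings
  res2 <- compute_residual(2 * refA$mean_waveform, refA)
  dec2 <- classify_outlier(res2, m, nz, refA)
  expect_equal(dec2$verdict, "flagged-pitfall")
  expect_false(dec2$retrieved)

  # 6-sigma noise bump absent from the recording: rejected
  bump <- rep(0, 250)
  bump[111:131] <- 6 * fx$sigma * exp(-0.5 * ((-10:10) / 3)^2)
  res3 <- compute_residual(refA$mean_waveform + bump, refA)
  m3 <- scan_recording(res3, fx$rec, epoch = 60)
  dec3 <- classify_outlier(res3, m3, nz, refA)
  expect_equal(dec3$verdict, "rejected-outlier")

  # conjunctive mode: matching alone no longer suffices
  dec_and <- classify_outlier(res, m, nz, refA, criteria = "and")
  expect_equal(dec_and$verdict, "rejected-outlier")
})

test_that("the scan never matches the outlier's own position", {
  fx <- sa_fixture(noise_sigma = 0, n_b = 1)   # single insertion
  refA <- refA_fixture()
  shift <- 40L
  addB <- c(fx$tplB[(shift + 1):250], rep(0, shift))
  res <- compute_residual(refA$mean_waveform + addB, refA)
  own_peak <- round(fx$times[1] * 10000) + 1L - shift
  m <- scan_recording(res, fx$rec, exclude_index = own_peak + shift,
                      epoch = 60)
  expect_equal(m$n_matches, 0)
})

test_that("unit assembly merges disjoint id sets with provenance", {
  m <- matrix(rnorm(100 * 250), 100, 250)
  ws <- ws_from_matrix(m, timestamps = sort(runif(100, 0, 60)))

  u0 <- assemble_unit(1:90, integer(0), ws, cluster_id = 1)
  expect_equal(nrow(u0$spikes), 90)
  expect_equal(u0$n_sa, 0)

  u <- assemble_unit(1:90, 91:100, ws, cluster_id = 2, cluster_size = 103)
  expect_equal(nrow(u$spikes), 100)
  expect_equal(u$fraction_retrieved, 0.1)
  expect_equal(u$fraction_retained, 100 / 103)
  expect_false(is.unsorted(u$spikes$timestamp))
  expect_equal(sum(u$spikes$provenance == "SA"), 10)

  expect_error(assemble_unit(1:10, 10:12, ws), "overlap")
})
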