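test_that("templates are unit-peak, peak-aligned, biphasic traces", {
  specs <- template_specs()
  for (i in seq_len(nrow(specs))) {
    tpl <- make_template(specs[i, ])
    expect_length(tpl, 250)
    expect_equal(which.max(tpl), 121)
    expect_equal(max(tpl), 1)
    expect_lt(min(tpl), 0)   # afterhyperpolarization present
  }

  # zero AHP depth: monophasic positive pulse
  mono <- make_template(template_specs(group_id = 1, peak_snr = 5,
                                       n_spikes = 1, ahp_frac = 0)[1, ])
  expect_gte(min(mono), 0)

  bad <- template_specs(group_id = 1, peak_snr = 5, n_spikes = 1)[1, ]
  bad$rise_ms <- -1
  expect_error(make_template(bad), "positive")
})

test_that("template amplitude at insertion is peak_snr times sigma", {
  spec <- template_specs(group_id = 1, peak_snr = 6, n_spikes = 5)
  ds <- generate_dataset(spec, epoch_s = 10, noise_sigma = 10,
                         noise_samples = rep(0, 1e5), min_spacing_s = 0.05,
                         seed = 81)
  p <- round(ds$ground_truth$time[1] * 10000) + 1L
  expect_equal(ds$recording$samples[p], 60)
})

test_that("noise generation hits the requested level and is seeded", {
  expect_equal(make_noise(0.1, 0), rep(0, 1000))
  x <- make_noise(10, 1, "white", seed = 82)
  expect_equal(median(abs(x)) / 0.6745, 1, tolerance = 0.02)
  expect_identical(make_noise(1, 2, seed = 5), make_noise(1, 2, seed = 5))

  ar <- make_noise(10, 3, "ar1", rho = 0.6, seed = 83)
  expect_equal(sd(ar), 3, tolerance = 0.05)
  expect_gt(cor(ar[-1], ar[-length(ar)]), 0.5)
  expect_error(make_noise(1, 1, "ar1", rho = 1), "rho")
})

test_that("datasets carry exact bookkeeping and forced synchrony", {
  specs <- template_specs(group_id = 1:2, peak_snr = c(4, 6),
                          n_spikes = c(100, 50), rise_ms = c(0.4, 0.5),
                          fall_ms = c(0.5, 0.6), ahp_frac = c(0.3, 0.4),
                          ahp_tau_ms = c(4, 5))
  ds <- generate_dataset(specs, epoch_s = 60, seed = 84)
  expect_equal(nrow(ds$ground_truth), 150)
  expect_equal(sum(ds$ground_truth$group_id == 1), 100)
  expect_false(is.unsorted(ds$ground_truth$time))
  # inserted times respect the snippet edges
  expect_gte(min(ds$ground_truth$time), 0.012)
  expect_lte(max(ds$ground_truth$time), 60 - 0.013)

  # same-group spacing enforced
  for (g in 1:2) {
    tg <- ds$ground_truth$time[ds$ground_truth$group_id == g]
    expect_gte(min(diff(sort(tg))), 0.02)
  }

  # without forced synchrony, near-coincidences are at chance level:
  # expected pairs ~ n_A * n_B * 2 * 1 ms / 60 s = 0.17
  tA <- ds$ground_truth$time[ds$ground_truth$group_id == 1]
  tB <- ds$ground_truth$time[ds$ground_truth$group_id == 2]
  close0 <- sum(vapply(tB, function(t) any(abs(tA - t) <= 0.001), logical(1)))
  expect_lte(close0, 3)

  # with sync(1, 2, f = 0.5, jitter 1 ms): at least 45% of B near an A
  ds_s <- generate_dataset(specs, epoch_s = 60, seed = 84,
                           sync = list(groups = c(1, 2), fraction = 0.5,
                                       jitter_ms = 1))
  tA <- ds_s$ground_truth$time[ds_s$ground_truth$group_id == 1]
  tB <- ds_s$ground_truth$time[ds_s$ground_truth$group_id == 2]
  close <- sum(vapply(tB, function(t) any(abs(tA - t) <= 0.0011), logical(1)))
  expect_gte(close, 0.45 * length(tB))

  # byte-identical reproduction under the same seed
  ds2 <- generate_dataset(specs, epoch_s = 60, seed = 84)
  expect_identical(ds$recording$samples, ds2$recording$samples)
  expect_identical(ds$ground_truth, ds2$ground_truth)

  expect_error(
    generate_dataset(template_specs(group_id = 1, peak_snr = 4,
                                    n_spikes = 10000),
                     epoch_s = 10, seed = 1),
    "infeasible|could not place")
})

test_that("accuracy scoring matches hand-computable constructions", {
  set.seed(85)
  gt <- tibble::tibble(time = c(sort(runif(80, 1, 59)), sort(runif(40, 1, 59))),
                       group_id = rep(1:2, c(80, 40)))
  gt <- dplyr::arrange(gt, time)

  u1 <- tibble::tibble(timestamp = sort(gt$time[gt$group_id == 1]))
  u2 <- tibble::tibble(timestamp = sort(gt$time[gt$group_id == 2]))
  perfect <- score_sorting(gt, list(u1, u2))
  expect_equal(perfect$by_group$accuracy, c(1, 1))
  expect_equal(perfect$by_group$false_positives, c(0, 0))

  empty <- score_sorting(gt, list(u1, tibble::tibble(timestamp = numeric())))
  expect_equal(empty$by_group$accuracy[2], 0)

  # drop a known 10% of group 1: accuracy exactly 0.90
  t1 <- sort(gt$time[gt$group_id == 1])
  u1_drop <- tibble::tibble(timestamp = t1[-seq(1, 80, by = 10)])
  dropped <- score_sorting(gt, list(u1_drop, u2))
  expect_equal(dropped$by_group$accuracy[1], 0.9)

  # ground-truth spikes are matched at most once
  u_dupe <- tibble::tibble(timestamp = rep(t1[1], 5))
  sc <- score_sorting(gt, list(u_dupe), mapping = 1L)
  expect_equal(sc$by_group$n_matched[1], 1)
  expect_equal(sc$by_group$false_positives[1], 4)
})
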