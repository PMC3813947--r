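test_that("refractory violations are counted and classified in bands", {
  expect_equal(refractory_check(cumsum(c(0, 0.005, 0.010)))$n_violations, 0)
  rc <- refractory_check(cumsum(c(0, 0.002, 0.005)))
  expect_equal(rc$n_violations, 1)
  expect_equal(rc$fraction, 0.5)
  expect_equal(rc$class, "violating")

  # deterministic three-band classification: 0 / <0.1% / >=0.1%
  clean_ts <- cumsum(rep(0.5, 2000))
  expect_equal(refractory_check(clean_ts)$class, "clean")
  one_bad <- cumsum(c(rep(0.5, 1999), 0.002))
  expect_equal(refractory_check(one_bad)$class, "marginal")   # 1/2000 = 0.05%
  many_bad <- cumsum(c(rep(0.5, 990), rep(0.002, 10)))
  expect_equal(refractory_check(many_bad)$class, "violating") # 1%

  expect_equal(refractory_check(c(1))$class, "undefined")

  # the histogram's left edge sits at the refractory bound
  expect_equal(round(log(0.003), 3), -5.809)
})

test_that("Scott-binned log-ISI histograms normalize exactly", {
  # ln-ISIs rescaled to sample SD exactly 1, n = 1000: h = 3.49/cbrt(1000)
  set.seed(71)
  z <- rnorm(1000)
  z <- (z - mean(z)) / sd(z)
  ts <- cumsum(c(1, exp(z)))   # 1001 timestamps -> the 1000 ISIs exp(z)
  hist <- isi_histogram(ts)
  expect_equal(hist$h, 3.49 * 1000^(-1 / 3), tolerance = 1e-12)
  expect_equal(hist$edges[1], log(0.003))
  expect_equal(sum(hist$bins$pd * hist$h), 1, tolerance = 1e-9)

  # lognormal ISIs: density on the ln scale approximates the standard normal
  set.seed(72)
  ts2 <- cumsum(exp(rnorm(1e4, 0, 1)))
  h2 <- isi_histogram(ts2)
  dev <- abs(h2$bins$pd - dnorm(h2$bins$mid, 0, 1))
  expect_lt(max(dev), 0.05)

  w <- capture_warnings(h_deg <- isi_histogram(cumsum(rep(1, 10))))
  expect_match(w, "30 ISIs", all = FALSE)
  expect_match(w, "degenerate", all = FALSE)
  expect_equal(nrow(h_deg$bins), 1)
  expect_error(isi_histogram(1), "ISI")
})

test_that("AICc evaluates the printed formula and orders by SSR", {
  expect_equal(aicc(20, 20, 3), 20 * log(1) + 6 + 24 / 16)
  expect_equal(aicc(20, 20, 3), 7.5)
  ssr <- c(1, 2, 5, 10)
  vals <- vapply(ssr, aicc, numeric(1), n_b = 30, K = 6)
  expect_true(all(diff(vals) > 0))
  expect_error(aicc(1, 5, 4), "n_b")
  expect_error(aicc(0, 30, 3), "positive")
})

test_that("Gaussian curve fits recover exact generating parameters", {
  # evaluate the model at a mode: y = a
  expect_equal(oligosort:::gaussian_mixture_curve(0.7, a = 0.4, b = 0.7, c = 1.2), 0.4)

  # noiseless single Gaussian sampled on a grid: parameters to 1e-4
  mid <- seq(-4, 4, by = 0.2)
  pd <- 0.4 * exp(-0.5 * mid^2)
  fit <- fit_gaussian_curve(hist_from_curve(mid, pd, 0.2), 1)
  expect_true(fit$converged)
  expect_equal(fit$params$a, 0.4, tolerance = 1e-4)
  expect_equal(fit$params$b, 0, tolerance = 1e-4)
  expect_equal(fit$params$c, 1, tolerance = 1e-4)
  expect_equal(fit$K, 3)

  # nesting: a 2-mode fit cannot be worse than 1-mode on bimodal data
  mid2 <- seq(-6, 6, by = 0.25)
  pd2 <- 0.3 * exp(-0.5 * ((mid2 + 2) / 0.8)^2) +
    0.25 * exp(-0.5 * ((mid2 - 2) / 0.8)^2)
  h2 <- hist_from_curve(mid2, pd2, 0.25)
  f1 <- fit_gaussian_curve(h2, 1)
  f2 <- fit_gaussian_curve(h2, 2)
  expect_lt(f2$ssr, f1$ssr)
})

test_that("AICc model selection picks the generating mode count", {
  # argmin arithmetic on stated values
  fake <- lapply(1:3, function(k) {
    structure(list(k_modes = k, aicc = c(10, 5, 7)[k], converged = TRUE),
              class = "oligo_gauss_fit")
  })
  sel <- select_isi_model(fake)
  expect_equal(sel$best_k, 2)
  expect_equal(sel$delta$delta_aicc[sel$delta$comparison == "2-1"], -5)

  only1 <- list(structure(list(k_modes = 1, aicc = 3, converged = TRUE),
                          class = "oligo_gauss_fit"),
                structure(list(k_modes = 2, aicc = Inf, converged = FALSE),
                          class = "oligo_gauss_fit"))
  expect_equal(select_isi_model(only1)$best_k, 1)
  none <- list(structure(list(k_modes = 1, aicc = Inf, converged = FALSE),
                         class = "oligo_gauss_fit"))
  expect_true(is.na(select_isi_model(none)$best_k))

  # simulation: unimodal log-ISIs are called unimodal in >= 8/10 replicates
  wins <- 0
  for (r in 1:10) {
    set.seed(700 + r)
    ts <- cumsum(exp(rnorm(2000, 0, 0.5)))
    h <- isi_histogram(ts)
    fits <- lapply(1:3, function(k) fit_gaussian_curve(h, k))
    if (identical(select_isi_model(fits)$best_k, 1L)) wins <- wins + 1
  }
  expect_gte(wins, 8)
})

test_that("feature-vs-ISI fits select and recover the generating model", {
  # exponential asymptote: y -> y0 as x -> Inf
  expect_equal(100 + (-30) * exp(-(1e9 - log(0.003)) / 1), 100)

  # synthetic exponential relaxation of peak amplitude vs preceding ln-ISI
  set.seed(73)
  n <- 2000
  isis <- exp(runif(n, log(0.01), log(10)))
  ts <- cumsum(isis)
  x <- log(isis)
  y <- 100 - 30 * exp(-(x - log(0.003)) / 1) + rnorm(n, 0, 2)
  unit <- list(spikes = tibble::tibble(spike = seq_len(n + 1),
                                       timestamp = c(0, ts)))
  ftab <- list(features = tibble::tibble(spike = seq_len(n + 1),
                                         peak_amplitude = c(y[1], y)))
  fit <- fit_feature_vs_isi(unit, ftab, "peak_amplitude")
  expect_equal(fit$model, "exponential")
  expect_false(fit$failed)
  expect_equal(fit$params$y0, 100, tolerance = 0.1)
  expect_equal(fit$params$a, -30, tolerance = 0.1)
  expect_equal(fit$params$t, 1, tolerance = 0.1)
  expect_equal(fit$params$x0, log(0.003))
  expect_lt(fit$p_value, 0.05)

  # pure noise: goodness fails, fit reported as failed
  set.seed(74)
  y_null <- rnorm(n, 50, 5)
  ftab0 <- list(features = tibble::tibble(spike = seq_len(n + 1),
                                          peak_amplitude = c(y_null[1], y_null)))
  fit0 <- fit_feature_vs_isi(unit, ftab0, "peak_amplitude")
  expect_true(fit0$failed)
})

test_that("the validation battery reaches the expected verdicts", {
  # single-fiber construction: lognormal ISIs, nothing under 3 ms
  set.seed(75)
  isis <- exp(rnorm(1500, 0, 0.6))
  isis <- isis[isis > 0.003]
  ts <- cumsum(isis)
  unit <- structure(
    list(spikes = tibble::tibble(spike = seq_along(ts), timestamp = ts,
                                 provenance = "T2"),
         cluster_id = 1),
    class = "oligo_unit")
  rep_ok <- validate_unit(unit)
  expect_equal(rep_ok$verdict, "single-fiber")
  expect_true(rep_ok$refractory$fraction < 0.001)
  expect_true(isTRUE(rep_ok$leftward_decline))

  # merged two-fiber construction: a 5-ms ISI mode spilling under 3 ms
  set.seed(76)
  short <- exp(rnorm(400, log(0.005), 0.45))
  long <- exp(rnorm(1100, log(1.5), 0.5))
  isis2 <- sample(c(short, long))
  ts2 <- cumsum(isis2)
  unit2 <- structure(
    list(spikes = tibble::tibble(spike = seq_along(ts2), timestamp = ts2,
                                 provenance = "T2"),
         cluster_id = 2),
    class = "oligo_unit")
  rep_bad <- validate_unit(unit2)
  expect_equal(rep_bad$verdict, "not-single-fiber")
  expect_gte(rep_bad$refractory$fraction, 0.001)

  # tiny unit: partial report, no verdict
  unit3 <- structure(
    list(spikes = tibble::tibble(spike = 1:10,
                                 timestamp = cumsum(rep(0.5, 10)),
                                 provenance = "T2"),
         cluster_id = 3),
    class = "oligo_unit")
  expect_equal(validate_unit(unit3)$verdict, "partial")
})
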