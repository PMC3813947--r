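#' Refractory-period check
#'
#' Interspike intervals shorter than the (arbitrary) 3-ms axonal refractory
#' period cannot come from a single fiber and are counted as violations.
#' Classes: `clean` (no violations), `marginal` (violating fraction below
#' 0.1%), `violating` (0.1% or more). Units with fraction < 0.1% are accepted
#' for the downstream single-fiber battery.
#'
#' @param timestamps Strictly increasing spike times in seconds (>= 2 spikes).
#' @param refractory Refractory period in seconds (default 0.003).
#' @return A list: `n_violations`, `fraction`, `class`.
#' @export
refractory_check <- function(timestamps, refractory = 0.003) {
  if (length(timestamps) < 2) {
    return(list(n_violations = NA_integer_, fraction = NA_real_,
                class = "undefined"))
  }
  isis <- diff(timestamps)
  n_viol <- sum(isis < refractory)
  frac <- n_viol / length(isis)
  cls <- if (n_viol == 0) "clean" else if (frac < 0.001) "marginal" else "violating"
  list(n_violations = n_viol, fraction = frac, class = cls)
}

#' Log-ISI probability histogram with Scott's bin width
#'
#' ISIs are natural-log transformed (compressing the long tail and expanding
#' the short-ISI range where refractory structure lives) and binned from
#' `ln(0.003)` = -5.809 (the refractory bound) up to the 99.9th percentile of
#' the log ISIs. The bin width is Scott's choice `h = 3.49 * s * n^(-1/3)`
#' with `s` the SD of the log ISIs and `n` their count. Probability density
#' is normalized so that `sum(pd * h) = 1` over the in-range ISIs.
#'
#' @param timestamps Spike times in seconds (>= 2; a warning below 31 ISIs).
#' @return An `oligo_isi_hist`: `$bins` tibble (`mid`, `pd`, `count`), `h`,
#'   `edges`, `n` (ISIs in range), `ln_isis` (all log ISIs), `isis`.
#' @export
isi_histogram <- function(timestamps) {
  isis <- diff(sort(timestamps))
  isis <- isis[isis > 0]
  n <- length(isis)
  if (n < 1) stop("need at least one positive ISI", call. = FALSE)
  if (n < 30) warning("fewer than 30 ISIs: histogram will be unstable",
                      call. = FALSE)
  ln_isis <- log(isis)
  s <- sd(ln_isis)
  lo <- log(0.003)
  hi <- as.numeric(quantile(ln_isis, 0.999, names = FALSE))
  if (is.na(s) || s == 0 || hi <= lo) {
    warning("degenerate ISI distribution: single-bin histogram", call. = FALSE)
    h <- max(1e-6, hi - lo, na.rm = TRUE)
    edges <- c(lo, lo + h)
  } else {
    h <- 3.49 * s * n^(-1 / 3)
    edges <- seq(lo, hi + h, by = h)
  }
  in_range <- ln_isis >= edges[1] & ln_isis < edges[length(edges)]
  counts <- graphics::hist(ln_isis[in_range], breaks = edges, plot = FALSE,
                           right = FALSE)$counts
  n_in <- sum(counts)
  pd <- if (n_in > 0) counts / (n_in * h) else counts * 0
  structure(
    list(bins = tibble::tibble(mid = (edges[-1] + edges[-length(edges)]) / 2,
                               pd = pd, count = counts),
         h = h, edges = edges, n = n_in, ln_isis = ln_isis, isis = isis),
    class = "oligo_isi_hist"
  )
}

#' @export
print.oligo_isi_hist <- function(x, ...) {
  cat(sprintf("<oligo_isi_hist> %d ISIs in %d bins (h = %.4f ln-s) over [%.3f, %.3f]\n",
              x$n, nrow(x$bins), x$h, x$edges[1], x$edges[length(x$edges)]))
  invisible(x)
}

#' Corrected Akaike information criterion for a least-squares fit
#'
#' `AICc = n_b * ln(SSR / n_b) + 2K + 2K(K + 1)/(n_b - K - 1)`, with `n_b`
#' the number of fitted points (histogram bins), `SSR` the sum of squared
#' residuals, and `K` the number of free parameters. Requires
#' `n_b > K + 1`.
#'
#' @param ssr Sum of squared residuals (> 0).
#' @param n_b Number of fitted points.
#' @param K Number of model parameters.
#' @return The AICc value.
#' @export
aicc <- function(ssr, n_b, K) {
  if (n_b <= K + 1) {
    stop("AICc undefined: need n_b > K + 1 (n_b = ", n_b, ", K = ", K, ")",
         call. = FALSE)
  }
  if (ssr <= 0) stop("`ssr` must be positive", call. = FALSE)
  n_b * log(ssr / n_b) + 2 * K + 2 * K * (K + 1) / (n_b - K - 1)
}

gaussian_mixture_curve <- function(x, a, b, c) {
  out <- numeric(length(x))
  for (i in seq_along(a)) out <- out + a[i] * exp(-0.5 * ((x - b[i]) / c[i])^2)
  out
}

# Greedy peak seeding: the k largest histogram bins at least `min_sep` apart.
seed_modes <- function(mid, pd, k, min_sep) {
  ord <- order(pd, decreasing = TRUE)
  picked <- integer(0)
  for (i in ord) {
    if (!length(picked) || all(abs(mid[i] - mid[picked]) >= min_sep)) {
      picked <- c(picked, i)
    }
    if (length(picked) == k) break
  }
  while (length(picked) < k) {  # fall back to spread seeds
    picked <- c(picked, which.min(abs(mid - (min(mid) +
      (length(picked) + 0.5) * diff(range(mid)) / k))))
  }
  picked
}

#' Fit a k-mode Gaussian curve to a log-ISI histogram
#'
#' Nonlinear least squares of `y = sum_i a_i * exp(-[(x - b_i)/c_i]^2 / 2)`
#' to the (bin midpoint, probability density) pairs, with `k` modes (1-3).
#' Initialization seeds the modes at the `k` largest histogram peaks (greedy,
#' minimum separation `2h`), amplitudes at the peak densities, and widths at
#' `h`; five jittered restarts guard against local minima. Fit quality is
#' summarized by the SSR, the printed-form [aicc()], and an adjusted
#' correlation (signed square root of adjusted R-squared of observed vs
#' predicted).
#'
#' @param hist An [isi_histogram()].
#' @param k_modes Number of Gaussian modes (1, 2 or 3).
#' @param n_restarts Jittered restarts (default 5).
#' @return An `oligo_gauss_fit`: `k_modes`, `params` tibble (`a`, `b`, `c`),
#'   `ssr`, `n_b`, `K = 3 * k_modes`, `aicc`, `adjusted_r`, `converged`,
#'   `fitted` (per-bin predictions).
#' @export
fit_gaussian_curve <- function(hist, k_modes, n_restarts = 5) {
  stopifnot(inherits(hist, "oligo_isi_hist"), k_modes %in% 1:3)
  mid <- hist$bins$mid
  pd <- hist$bins$pd
  n_b <- length(mid)
  K <- 3L * k_modes
  fail <- structure(
    list(k_modes = k_modes, params = NULL, ssr = NA_real_, n_b = n_b, K = K,
         aicc = Inf, adjusted_r = NA_real_, converged = FALSE, fitted = NULL),
    class = "oligo_gauss_fit"
  )
  if (n_b <= K + 1) return(fail)
  peaks <- seed_modes(mid, pd, k_modes, 2 * hist$h)
  base_start <- list(a = pmax(pd[peaks], 1e-6), b = mid[peaks],
                     c = rep(hist$h, k_modes))
  df <- data.frame(x = mid, y = pd)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    start <- base_start
    if (r > 1) {
      jit <- with_local_seed(1000 + r, list(
        b = rnorm(k_modes, 0, hist$h), c = runif(k_modes, 0.5, 3)
      ))
      start$b <- start$b + jit$b
      start$c <- start$c * jit$c
    }
    names(start$a) <- paste0("a", seq_len(k_modes))
    names(start$b) <- paste0("b", seq_len(k_modes))
    names(start$c) <- paste0("c", seq_len(k_modes))
    terms <- paste0("a", 1:k_modes, " * exp(-0.5 * ((x - b", 1:k_modes,
                    ") / c", 1:k_modes, ")^2)", collapse = " + ")
    fml <- stats::as.formula(paste("y ~", terms))
    fit <- tryCatch(
      minpack.lm::nlsLM(
        fml, data = df,
        start = c(as.list(start$a), as.list(start$b), as.list(start$c)),
        # width floor of one bin: a mode narrower than the histogram's own
        # resolution is noise-chasing, not structure
        lower = c(rep(1e-9, k_modes), rep(min(mid) - 5, k_modes),
                  rep(hist$h, k_modes)),
        upper = c(rep(Inf, k_modes), rep(max(mid) + 5, k_modes),
                  rep(diff(range(mid)) + 1, k_modes)),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      cf <- coef(fit)
      bs <- unname(cf[paste0("b", 1:k_modes)])
      cs <- unname(cf[paste0("c", 1:k_modes)])
      # Each fitted mode must be a resolvable hump: equal Gaussians closer
      # than twice their width merge into a single maximum, so a solution
      # with modes nearer than 2 x the larger width is a lower-order shape
      # masquerading as k modes (typically a noise-chasing shoulder bump).
      degenerate <- FALSE
      if (k_modes > 1) {
        for (i in 1:(k_modes - 1)) {
          for (j in (i + 1):k_modes) {
            if (abs(bs[i] - bs[j]) < 2 * max(cs[i], cs[j])) degenerate <- TRUE
          }
        }
      }
      if (!degenerate) {
        ssr <- sum(stats::residuals(fit)^2)
        if (is.null(best) || ssr < best$ssr) best <- list(fit = fit, ssr = ssr)
      }
    }
  }
  if (is.null(best)) return(fail)
  cf <- coef(best$fit)
  a <- unname(cf[paste0("a", 1:k_modes)])
  b <- unname(cf[paste0("b", 1:k_modes)])
  cc <- unname(cf[paste0("c", 1:k_modes)])
  ord <- order(b)
  fitted_pd <- gaussian_mixture_curve(mid, a, b, cc)
  structure(
    list(k_modes = k_modes,
         params = tibble::tibble(a = a[ord], b = b[ord], c = cc[ord]),
         ssr = best$ssr, n_b = n_b, K = K,
         aicc = aicc(max(best$ssr, 1e-300), n_b, K),
         adjusted_r = adjusted_r(pd, fitted_pd, K),
         converged = TRUE, fitted = fitted_pd),
    class = "oligo_gauss_fit"
  )
}

# Signed square root of adjusted R-squared of observed vs predicted.
adjusted_r <- function(obs, pred, K) {
  n <- length(obs)
  if (n - K - 1 <= 0 || sd(obs) == 0 || sd(pred) == 0) return(NA_real_)
  r <- cor(obs, pred)
  r2_adj <- 1 - (1 - r^2) * (n - 1) / (n - K - 1)
  sign(r) * sqrt(max(r2_adj, 0))
}

#' @export
print.oligo_gauss_fit <- function(x, ...) {
  if (!x$converged) {
    cat(sprintf("<oligo_gauss_fit> k = %d: FAILED\n", x$k_modes))
    return(invisible(x))
  }
  cat(sprintf("<oligo_gauss_fit> k = %d, SSR = %.4g, AICc = %.2f, adj r = %.4f\n",
              x$k_modes, x$ssr, x$aicc, x$adjusted_r))
  print(as.data.frame(x$params), row.names = FALSE)
  invisible(x)
}

#' Select the best Gaussian mode count by AICc
#'
#' @param fits List of [fit_gaussian_curve()] results (typically k = 1..3).
#' @return A list: `best_k` (argmin AICc among converged fits; `NA` when all
#'   failed), `best` (the winning fit), and `delta` tibble of all pairwise
#'   AICc differences (`comparison` like `"2-1"`, `delta_aicc`).
#' @export
select_isi_model <- function(fits) {
  ks <- vapply(fits, function(f) f$k_modes, numeric(1))
  ai <- vapply(fits, function(f) f$aicc, numeric(1))
  conv <- vapply(fits, function(f) f$converged, logical(1))
  delta <- if (length(fits) >= 2) {
    pairs <- utils::combn(seq_along(fits), 2)
    tibble::tibble(
      comparison = paste0(ks[pairs[2, ]], "-", ks[pairs[1, ]]),
      delta_aicc = ai[pairs[2, ]] - ai[pairs[1, ]]
    )
  } else {
    tibble::tibble(comparison = character(), delta_aicc = numeric())
  }
  if (!any(conv)) {
    return(list(best_k = NA_integer_, best = NULL, delta = delta))
  }
  best_i <- which(conv)[which.min(ai[conv])]
  list(best_k = as.integer(ks[best_i]), best = fits[[best_i]], delta = delta)
}

#' Preceding-ISI dependence of a waveform feature
#'
#' Waveform shape is not stationary: features can relax as a function of the
#' interval since the previous spike (e.g. sodium-channel availability after
#' short intervals). Per-spike feature values are binned by their preceding
#' log ISI (Scott bins), and the per-bin means are fitted by two competing
#' models: an exponential relaxation `y = y0 + a * exp(-(x - x0)/t)` (with
#' `x0` fixed at `ln(0.003)` to remove the `a * exp(x0/t)` redundancy; free
#' parameters `y0`, `a`, `t`, so K = 3) and a line `y = m x + b` (K = 2). The
#' model with the lower [aicc()] wins unless its goodness test fails while the
#' other's passes. Goodness of fit uses the Spearman correlation `r` between
#' observed and predicted bin means and the t-statistic
#' `t = r * sqrt((n_b - K - 1)/(1 - r^2))` with a two-sided p; the fit is
#' `failed` when p >= 0.05.
#'
#' @param unit An [assemble_unit()] result (or any list with `$spikes` having
#'   `timestamp`).
#' @param features The [extract_features()] table covering the unit's spikes
#'   (matched on the `spike` column).
#' @param feature_name One of the six feature columns.
#' @return An `oligo_feature_isi`: `feature_name`, `model` (`"exponential"`
#'   or `"linear"`), `params`, `aicc_exp`, `aicc_lin`, `spearman_r`, `t_stat`,
#'   `p_value`, `failed`, `bins` tibble (`x`, `y`, `pred`), `n_b`.
#' @export
fit_feature_vs_isi <- function(unit, features, feature_name = "peak_amplitude") {
  stopifnot(feature_name %in% feature_names())
  spikes <- unit$spikes
  ft <- features$features
  vals <- ft[[feature_name]][match(spikes$spike, ft$spike)]
  ts <- spikes$timestamp
  pre_isi <- c(NA, diff(ts))
  ok <- !is.na(pre_isi) & pre_isi > 0 & !is.na(vals)
  x_all <- log(pre_isi[ok])
  y_all <- vals[ok]
  fail <- structure(
    list(feature_name = feature_name, model = NA_character_, params = NULL,
         aicc_exp = NA_real_, aicc_lin = NA_real_, spearman_r = NA_real_,
         t_stat = NA_real_, p_value = NA_real_, failed = TRUE, bins = NULL,
         n_b = 0L),
    class = "oligo_feature_isi"
  )
  if (length(x_all) < 10 || sd(x_all) == 0) return(fail)

  h <- 3.49 * sd(x_all) * length(x_all)^(-1 / 3)
  edges <- seq(min(x_all), max(x_all) + h, by = h)
  bin_id <- findInterval(x_all, edges, rightmost.closed = TRUE)
  agg <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(bin = bin_id, x = x_all, y = y_all),
                    .data$bin),
    x = mean(.data$x), y = mean(.data$y), n = dplyr::n(), .groups = "drop"
  )
  xb <- agg$x; yb <- agg$y
  n_b <- length(xb)
  if (n_b < 5) return(fail)  # need n_b > K + 1 for the exponential (K = 3)

  x0 <- log(0.003)
  lin <- lm(yb ~ xb)
  ssr_lin <- sum(stats::residuals(lin)^2)
  aicc_lin <- aicc(max(ssr_lin, 1e-300), n_b, 2)
  pred_lin <- stats::fitted(lin)

  exp_fit <- NULL
  t_starts <- c(0.5, 1, 2, 5)
  for (t0 in t_starts) {
    f <- tryCatch(
      minpack.lm::nlsLM(
        yb ~ y0 + a * exp(-(xb - x0) / t),
        start = list(y0 = mean(tail(yb, 3)),
                     a = yb[1] - mean(tail(yb, 3)), t = t0),
        lower = c(-Inf, -Inf, 1e-3),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(f)) {
      ssr <- sum(stats::residuals(f)^2)
      if (is.null(exp_fit) || ssr < exp_fit$ssr) exp_fit <- list(fit = f, ssr = ssr)
    }
  }
  aicc_exp <- if (is.null(exp_fit)) Inf else aicc(max(exp_fit$ssr, 1e-300), n_b, 3)

  goodness <- function(pred, K) {
    if (sd(pred) == 0 || sd(yb) == 0) {
      return(list(r = 0, t = 0, p = 1))
    }
    r <- suppressWarnings(cor(yb, pred, method = "spearman"))
    if (is.na(r) || abs(r) >= 1) r <- sign(r) * 0.999999
    df <- n_b - K - 1
    t <- r * sqrt(df / (1 - r^2))
    list(r = r, t = t, p = 2 * pt(-abs(t), df))
  }
  g_lin <- goodness(pred_lin, 2)
  g_exp <- if (is.null(exp_fit)) list(r = NA, t = NA, p = 1)
           else goodness(predict(exp_fit$fit), 3)

  pick_exp <- aicc_exp < aicc_lin
  if (pick_exp && g_exp$p >= 0.05 && g_lin$p < 0.05) pick_exp <- FALSE
  if (!pick_exp && g_lin$p >= 0.05 && !is.null(exp_fit) && g_exp$p < 0.05) {
    pick_exp <- TRUE
  }
  if (pick_exp && is.null(exp_fit)) pick_exp <- FALSE

  if (pick_exp) {
    cf <- coef(exp_fit$fit)
    params <- tibble::tibble(y0 = cf[["y0"]], a = cf[["a"]], x0 = x0,
                             t = cf[["t"]])
    g <- g_exp; model <- "exponential"; pred <- predict(exp_fit$fit)
  } else {
    cf <- coef(lin)
    params <- tibble::tibble(m = cf[[2]], b = cf[[1]])
    g <- g_lin; model <- "linear"; pred <- pred_lin
  }
  structure(
    list(feature_name = feature_name, model = model, params = params,
         aicc_exp = aicc_exp, aicc_lin = aicc_lin,
         spearman_r = g$r, t_stat = g$t, p_value = g$p,
         failed = g$p >= 0.05,
         bins = tibble::tibble(x = xb, y = yb, pred = pred), n_b = n_b),
    class = "oligo_feature_isi"
  )
}

#' @export
print.oligo_feature_isi <- function(x, ...) {
  if (is.na(x$model)) {
    cat(sprintf("<oligo_feature_isi> %s: insufficient data\n", x$feature_name))
    return(invisible(x))
  }
  cat(sprintf("<oligo_feature_isi> %s ~ preceding ln-ISI: %s model, r = %.3f, t = %.2f, p = %.3g%s\n",
              x$feature_name, x$model, x$spearman_r, x$t_stat, x$p_value,
              if (x$failed) " [goodness FAILED]" else ""))
  invisible(x)
}

#' Full single-fiber validation battery
#'
#' Combines three lines of evidence that a unit's spikes come from one fiber:
#' (1) a clean refractory period (violating ISI fraction < 0.1%); (2) a
#' log-ISI probability distribution well described by a 1-3 mode Gaussian
#' curve whose fitted density declines promptly toward the refractory bound
#' (fitted pd at `ln(0.003)` below 10% of the smallest mode's peak — a
#' missing decline betrays overlapped spikes whose short ISIs were simply
#' never detected); and (3) a preceding-ISI dependence of at least one
#' waveform feature (supporting but not required — many genuine single fibers
#' show none).
#'
#' @param unit An [assemble_unit()] result.
#' @param features Optional [extract_features()] table for criterion (3).
#' @param feature_names_to_test Features to fit against preceding ISI
#'   (default `"peak_amplitude"`, the most sensitive).
#' @param decline_frac Leftward-decline threshold as a fraction of the
#'   smallest-mode peak (default 0.1).
#' @return An `oligo_validation`: `refractory`, `isi_fit` (best Gaussian fit),
#'   `delta_aicc`, `leftward_decline` (logical + raw values), `feature_fits`,
#'   `verdict` (`"single-fiber"`, `"not-single-fiber"`, or `"partial"`), and
#'   `reasons`.
#' @export
validate_unit <- function(unit, features = NULL,
                          feature_names_to_test = "peak_amplitude",
                          decline_frac = 0.1) {
  ts <- unit$spikes$timestamp
  refr <- refractory_check(ts)
  if (length(ts) < 30) {
    return(structure(
      list(refractory = refr, isi_fit = NULL, delta_aicc = NULL,
           leftward_decline = NA, feature_fits = list(),
           verdict = "partial",
           reasons = sprintf("only %d spikes: full battery needs >= 30",
                             length(ts))),
      class = "oligo_validation"
    ))
  }
  hist <- isi_histogram(ts)
  fits <- lapply(1:3, function(k) fit_gaussian_curve(hist, k))
  sel <- select_isi_model(fits)
  decline <- NA
  decline_vals <- c(pd_at_refractory = NA_real_, smallest_mode_peak = NA_real_)
  if (!is.null(sel$best) && sel$best$converged) {
    p <- sel$best$params
    pd_left <- gaussian_mixture_curve(log(0.003), p$a, p$b, p$c)
    decline_vals <- c(pd_at_refractory = pd_left,
                      smallest_mode_peak = min(p$a))
    decline <- pd_left < decline_frac * min(p$a)
  }
  feature_fits <- list()
  if (!is.null(features)) {
    feature_fits <- lapply(feature_names_to_test, function(fn) {
      fit_feature_vs_isi(unit, features, fn)
    })
    names(feature_fits) <- feature_names_to_test
  }
  feat_support <- any(vapply(feature_fits,
                             function(f) isFALSE(f$failed), logical(1)))
  refr_ok <- !is.na(refr$fraction) && refr$fraction < 0.001
  reasons <- character(0)
  if (!refr_ok) {
    reasons <- c(reasons, sprintf("refractory violations: %.2f%% of ISIs",
                                  100 * refr$fraction))
  }
  if (isFALSE(decline)) {
    reasons <- c(reasons,
                 "ISI density does not decline toward the refractory bound")
  }
  if (is.na(decline)) reasons <- c(reasons, "no converged ISI Gaussian fit")
  verdict <- if (refr_ok && isTRUE(decline)) "single-fiber" else "not-single-fiber"
  if (length(reasons) == 0) {
    reasons <- if (feat_support) {
      "clean refractory period; declining ISI density; feature-ISI dependence present"
    } else {
      "clean refractory period; declining ISI density"
    }
  }
  structure(
    list(refractory = refr, isi_fit = sel$best, delta_aicc = sel$delta,
         best_k = sel$best_k, leftward_decline = decline,
         decline_values = decline_vals, feature_fits = feature_fits,
         feature_support = feat_support, verdict = verdict,
         reasons = reasons),
    class = "oligo_validation"
  )
}

#' @export
print.oligo_validation <- function(x, ...) {
  cat(sprintf("<oligo_validation> verdict: %s\n", x$verdict))
  if (!is.na(x$refractory$fraction)) {
    cat(sprintf("  refractory: %s (%d violations, %.3f%%)\n",
                x$refractory$class, x$refractory$n_violations,
                100 * x$refractory$fraction))
  }
  if (!is.null(x$isi_fit)) {
    cat(sprintf("  ISI model: %d Gaussian mode(s), AICc = %.2f\n",
                x$isi_fit$k_modes, x$isi_fit$aicc))
  }
  cat("  ", paste(x$reasons, collapse = "; "), "\n", sep = "")
  invisible(x)
}
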