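#' Template specifications for the synthetic generator
#'
#' Each row describes one spike group: its peak amplitude in units of the
#' background-noise SD (`peak_snr`), how many spikes to insert per epoch, and
#' the biphasic shape parameters (Gaussian rise to an overshoot, fast
#' exponential fall into an afterhyperpolarization that relaxes slowly, with
#' an optional rebound bump).
#'
#' The default four groups span peak SNR 2-6 with slightly different shapes,
#' which is the regime where sorting accuracy transitions from chance to
#' near-perfect.
#'
#' @param group_id Integer ids.
#' @param peak_snr Peak amplitudes in sigma_n units (> 0).
#' @param n_spikes Insertions per epoch.
#' @param rise_ms,fall_ms Rise (Gaussian SD) and fall (exponential time
#'   constant) in ms.
#' @param ahp_frac Afterhyperpolarization depth as a fraction of the peak
#'   (0 = monophasic).
#' @param ahp_tau_ms AHP relaxation time constant in ms.
#' @param rebound_frac Optional rebound amplitude fraction (default 0).
#' @return A tibble of template specs.
#' @export
template_specs <- function(group_id = 1:4,
                           peak_snr = c(2, 3, 4, 6),
                           n_spikes = rep(120L, length(group_id)),
                           rise_ms = c(0.35, 0.45, 0.40, 0.55),
                           fall_ms = c(0.45, 0.60, 0.80, 0.55),
                           ahp_frac = c(0.25, 0.40, 0.30, 0.45),
                           ahp_tau_ms = c(3, 5, 4, 6),
                           rebound_frac = rep(0, length(group_id))) {
  n <- length(group_id)
  tibble::tibble(group_id = as.integer(group_id),
                 peak_snr = rep_len(peak_snr, n),
                 n_spikes = as.integer(rep_len(n_spikes, n)),
                 rise_ms = rep_len(rise_ms, n),
                 fall_ms = rep_len(fall_ms, n),
                 ahp_frac = rep_len(ahp_frac, n),
                 ahp_tau_ms = rep_len(ahp_tau_ms, n),
                 rebound_frac = rep_len(rebound_frac, n))
}

#' Build one spike template
#'
#' Unit-peak 25-ms biphasic trace with the peak exactly at the alignment
#' sample (121st at 10 kHz): a Gaussian rise, then
#' `(1 + ahp) * exp(-t/fall) - ahp * exp(-t/ahp_tau)` which falls through
#' zero into the afterhyperpolarization and relaxes back, plus an optional
#' Gaussian rebound bump. Scaled to `peak_snr * sigma_n` at insertion.
#'
#' @param spec One row of [template_specs()] (list or one-row data frame).
#' @param rate Sample rate (default 10000).
#' @return Numeric vector of length `round(0.025 * rate)` with maximum 1 at
#'   the alignment sample.
#' @export
make_template <- function(spec, rate = 10000) {
  spec <- as.list(spec)
  if (spec$rise_ms <= 0 || spec$fall_ms <= 0 || spec$ahp_tau_ms <= 0 ||
      spec$ahp_frac < 0) {
    stop("template shape parameters must be positive (ahp_frac >= 0)",
         call. = FALSE)
  }
  n_pre <- ms_to_samples(12, rate)
  n_post <- ms_to_samples(13, rate)
  align <- n_pre + 1L
  tm <- (seq_len(n_pre + n_post) - align) / rate * 1000  # ms relative to peak
  v <- numeric(length(tm))
  pre <- tm <= 0
  v[pre] <- exp(-0.5 * (tm[pre] / spec$rise_ms)^2)
  ahp <- spec$ahp_frac
  v[!pre] <- (1 + ahp) * exp(-tm[!pre] / spec$fall_ms) -
    ahp * exp(-tm[!pre] / spec$ahp_tau_ms)
  reb <- spec$rebound_frac %||% 0
  if (reb > 0) {
    v <- v + reb * exp(-0.5 * ((tm - 4 * spec$ahp_tau_ms) / 2)^2)
  }
  v <- v / max(v)
  stopifnot(which.max(v) == align)
  v
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate background noise
#'
#' Stationary Gaussian noise, white or AR(1) with lag-1 correlation `rho`
#' (innovation variance scaled so the marginal SD is `sigma`). Substitutes
#' for recorded no-spiking background; a user-supplied noise recording can be
#' passed to [generate_dataset()] instead.
#'
#' @param duration_s Duration in seconds.
#' @param sigma Marginal SD in uV (>= 0).
#' @param model `"white"` or `"ar1"`.
#' @param rho AR(1) coefficient, |rho| < 1.
#' @param rate Sample rate (default 10000).
#' @param seed Optional seed for a reproducible trace (restores the caller's
#'   RNG state).
#' @return Numeric vector of `round(duration_s * rate)` samples.
#' @export
make_noise <- function(duration_s, sigma, model = c("white", "ar1"),
                       rho = 0.5, rate = 10000, seed = NULL) {
  model <- match.arg(model)
  stopifnot(sigma >= 0)
  if (model == "ar1" && abs(rho) >= 1) {
    stop("|rho| must be < 1 for stationary AR(1) noise", call. = FALSE)
  }
  n <- round(duration_s * rate)
  gen <- function() {
    if (sigma == 0) return(numeric(n))
    if (model == "white") {
      rnorm(n, 0, sigma)
    } else {
      innov <- rnorm(n, 0, sigma * sqrt(1 - rho^2))
      innov[1] <- rnorm(1, 0, sigma)
      as.numeric(stats::filter(innov, rho, method = "recursive"))
    }
  }
  if (is.null(seed)) gen() else with_local_seed(seed, gen())
}

# Draw `n` event times in [lo, hi] with minimum spacing, by oversampling and
# greedy thinning.
draw_spaced_times <- function(n, lo, hi, min_spacing) {
  if (n * min_spacing > 0.5 * (hi - lo)) {
    stop(sprintf(
      "infeasible density: %d spikes with %.3f s spacing need more than the %.1f s epoch",
      n, min_spacing, hi - lo), call. = FALSE)
  }
  for (attempt in 1:20) {
    cand <- sort(runif(3 * n + 10, lo, hi))
    kept <- cand[1]
    for (t in cand[-1]) {
      if (t - kept[length(kept)] >= min_spacing) kept <- c(kept, t)
      if (length(kept) == n) break
    }
    if (length(kept) == n) return(kept)
  }
  stop("could not place spikes at the requested density", call. = FALSE)
}

#' Generate a ground-truth synthetic recording
#'
#' Emulates the benchmark construction: unit-peak templates are scaled to
#' `peak_snr * sigma` and summed into a background-noise trace at
#' uniform-random times (same-group spacing enforced), over a configurable
#' epoch. With a `sync` configuration, a fraction of one group's spikes is
#' re-placed within a small jitter of randomly chosen spikes of another
#' group, manufacturing the near-coincident firing (and hence overlapped
#' complex waveforms) characteristic of synchronous sympathetic discharge.
#'
#' @param specs A [template_specs()] tibble.
#' @param epoch_s Epoch length in seconds (default 120; 1800 is the
#'   full-length preset).
#' @param noise_sigma Background SD in uV (default 10).
#' @param noise_model,rho Passed to [make_noise()].
#' @param noise_samples Optional user-supplied noise trace (overrides the
#'   parametric noise; recycled/truncated to the epoch).
#' @param sync `NULL`, or `list(groups = c(A, B), fraction = f, jitter_ms = j)`:
#'   fraction `f` of group-B spikes is re-placed within `±j` ms of random
#'   group-A spikes.
#' @param min_spacing_s Same-group minimum spacing (default 0.02 s).
#' @param rate Sample rate (default 10000).
#' @param seed RNG seed; the dataset is byte-identical given the same seed.
#' @return An `oligo_synth`: `recording`, `ground_truth` tibble (`time`,
#'   `group_id`), `templates` (list of unit traces), `specs`, `noise_sigma`,
#'   `sync`, `seed`.
#' @export
generate_dataset <- function(specs, epoch_s = 120, noise_sigma = 10,
                             noise_model = "white", rho = 0.5,
                             noise_samples = NULL, sync = NULL,
                             min_spacing_s = 0.02, rate = 10000, seed = 1) {
  templates <- lapply(seq_len(nrow(specs)), function(i) {
    make_template(specs[i, ], rate)
  })
  names(templates) <- specs$group_id
  n_pre <- ms_to_samples(12, rate)
  n_post <- ms_to_samples(13, rate)
  lo <- (n_pre + 1) / rate
  hi <- epoch_s - (n_post + 1) / rate

  with_local_seed(seed, {
    noise <- if (!is.null(noise_samples)) {
      ns <- rep_len(noise_samples, round(epoch_s * rate))
      as.numeric(ns)
    } else {
      make_noise(epoch_s, noise_sigma, noise_model, rho, rate)
    }
    times <- lapply(seq_len(nrow(specs)), function(i) {
      draw_spaced_times(specs$n_spikes[i], lo, hi, min_spacing_s)
    })
    names(times) <- as.character(specs$group_id)

    if (!is.null(sync)) {
      ga <- as.character(sync$groups[1]); gb <- as.character(sync$groups[2])
      tb <- times[[gb]]
      n_move <- round(sync$fraction * length(tb))
      if (n_move > 0) {
        move <- sample(seq_along(tb), n_move)
        anchors <- sample(times[[ga]], n_move, replace = n_move > length(times[[ga]]))
        jit <- runif(n_move, -sync$jitter_ms, sync$jitter_ms) / 1000
        tb[move] <- pmin(pmax(anchors + jit, lo), hi)
        times[[gb]] <- sort(tb)
      }
    }

    x <- noise
    gt <- purrr::map_dfr(seq_len(nrow(specs)), function(i) {
      g <- as.character(specs$group_id[i])
      peak_samples <- round(times[[g]] * rate) + 1L
      amp <- specs$peak_snr[i] * noise_sigma
      for (p in peak_samples) {
        idx <- (p - n_pre):(p + n_post - 1L)
        x[idx] <<- x[idx] + amp * templates[[g]]
      }
      tibble::tibble(time = (peak_samples - 1L) / rate,
                     group_id = specs$group_id[i])
    })
    gt <- dplyr::arrange(gt, .data$time)
    structure(
      list(recording = recording(x, rate,
                                 meta = list(source = "synthetic", seed = seed)),
           ground_truth = gt, templates = templates, specs = specs,
           noise_sigma = noise_sigma, sync = sync, seed = seed),
      class = "oligo_synth"
    )
  })
}

#' @export
print.oligo_synth <- function(x, ...) {
  cat(sprintf("<oligo_synth> %.0f s, %d groups, %d spikes, noise sigma = %g uV%s (seed %d)\n",
              duration(x$recording), nrow(x$specs), nrow(x$ground_truth),
              x$noise_sigma,
              if (is.null(x$sync)) "" else
                sprintf(", sync %s<->%s f=%.2f", x$sync$groups[1],
                        x$sync$groups[2], x$sync$fraction),
              x$seed))
  invisible(x)
}

#' Score sorted units against ground truth
#'
#' Each unit is assigned to one ground-truth group (majority vote over
#' nearest-time matches unless `mapping` is given), then matched one-to-one
#' to that group's true spikes by greedy nearest-time pairing within
#' `tolerance`. Accuracy is matched true spikes / true spikes; unmatched unit
#' spikes count as false positives.
#'
#' @param ground_truth Tibble with `time` and `group_id`.
#' @param units List of [assemble_unit()] results (or tibbles with
#'   `timestamp`).
#' @param mapping Optional integer vector: `mapping[i]` = group for unit i.
#' @param tolerance Matching tolerance in seconds (default 0.0005).
#' @return An `oligo_accuracy`: `$by_group` tibble (`group_id`, `n_true`,
#'   `n_matched`, `accuracy`, `false_positives`), `$mapping`, `tolerance`.
#' @export
score_sorting <- function(ground_truth, units, mapping = NULL,
                          tolerance = 0.0005) {
  unit_times <- lapply(units, function(u) {
    if (inherits(u, "oligo_unit")) u$spikes$timestamp else u$timestamp
  })
  groups <- sort(unique(ground_truth$group_id))

  if (is.null(mapping)) {
    mapping <- vapply(unit_times, function(ts) {
      if (length(ts) == 0) return(NA_integer_)
      near <- vapply(ts, function(t) {
        d <- abs(ground_truth$time - t)
        i <- which.min(d)
        if (d[i] <= tolerance) ground_truth$group_id[i] else NA_integer_
      }, numeric(1))
      if (all(is.na(near))) NA_integer_ else
        as.integer(names(which.max(table(near))))
    }, integer(1))
  }
  dup <- mapping[!is.na(mapping)][duplicated(mapping[!is.na(mapping)])]
  if (length(dup)) {
    warning("multiple units mapped to group(s) ", paste(unique(dup), collapse = ", "),
            ": counted jointly", call. = FALSE)
  }

  by_group <- purrr::map_dfr(groups, function(g) {
    truth <- sort(ground_truth$time[ground_truth$group_id == g])
    pred <- sort(unlist(unit_times[which(mapping == g)]))
    n_true <- length(truth)
    if (length(pred) == 0 || n_true == 0) {
      return(tibble::tibble(group_id = g, n_true = n_true, n_matched = 0L,
                            accuracy = 0, false_positives = length(pred)))
    }
    # Greedy one-to-one nearest-time matching within tolerance.
    pairs <- expand.grid(ti = seq_along(truth), pi = seq_along(pred))
    pairs$d <- abs(truth[pairs$ti] - pred[pairs$pi])
    pairs <- pairs[pairs$d <= tolerance, ]
    pairs <- pairs[order(pairs$d), ]
    used_t <- logical(length(truth)); used_p <- logical(length(pred))
    n_matched <- 0L
    for (i in seq_len(nrow(pairs))) {
      ti <- pairs$ti[i]; pi <- pairs$pi[i]
      if (!used_t[ti] && !used_p[pi]) {
        used_t[ti] <- TRUE; used_p[pi] <- TRUE
        n_matched <- n_matched + 1L
      }
    }
    tibble::tibble(group_id = g, n_true = n_true, n_matched = n_matched,
                   accuracy = n_matched / n_true,
                   false_positives = sum(!used_p))
  })
  structure(
    list(by_group = by_group, mapping = mapping, tolerance = tolerance),
    class = "oligo_accuracy"
  )
}

#' @export
print.oligo_accuracy <- function(x, ...) {
  cat(sprintf("<oligo_accuracy> tolerance ±%.2g ms\n", 1000 * x$tolerance))
  print(as.data.frame(x$by_group), row.names = FALSE)
  invisible(x)
}
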